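# Synthetic structure + reactivity generator ---------------------------------
#
# Idealized A-form-like helical models with exactly known ground truth:
# every Watson-Crick-Franklin pair contributes its canonical hydrogen
# bonds (2 for A-U, 3 for G-C) and nothing else, paired reactive atoms
# (N1 of A, N3 of C) are fully buried, and unpaired bases (hairpin
# loops, bulged positions) expose them.  Nucleotides are schematic:
# base ring + exocyclic heteroatoms, the glycosidic C1', and a reduced
# carbon "sugar" (two cap carbons sandwiching the base face plus C4');
# no phosphodiester backbone is modelled.  Helical parameters are fixed
# constants so fixtures are stable across releases.

.RISE <- 2.81
.TWIST <- 32.7 * pi / 180
.PAIR_SPAN <- 5.65          # distance between the two WCF-edge frames
.HELIX_AXIS <- c(-10, 3)    # xy position of the helix axis in the pair frame
.COMP <- c(A = "U", U = "A", G = "C", C = "G")

# regular hexagon of ring atoms, bond length 1.38 A, first atom at angle 0
.ring_hex <- function(order, R = 1.38) {
  ang <- seq(0, 300, by = 60) * pi / 180
  m <- cbind(R * cos(ang), R * sin(ang))
  rownames(m) <- order
  m
}

.exo <- function(ring, at, bl) {
  v <- ring[at, ]
  v / sqrt(sum(v^2)) * (sqrt(sum(v^2)) + bl)
}

# three pentagon vertices fused on ring edge a-b, outward from the origin
.pent <- function(ring, a, b, side = 1.38) {
  A <- ring[a, ]; B <- ring[b, ]
  mid <- (A + B) / 2
  apo <- side / (2 * tan(pi / 5))
  Rp <- side / (2 * sin(pi / 5))
  cen <- mid + mid / sqrt(sum(mid^2)) * apo
  angA <- atan2(A[2] - cen[2], A[1] - cen[1])
  angB <- atan2(B[2] - cen[2], B[1] - cen[1])
  d <- (angB - angA) %% (2 * pi); if (d > pi) d <- d - 2 * pi
  step <- -sign(d) * 2 * pi / 5
  t(sapply(1:3, function(k) cen + Rp * c(cos(angA + k * step),
                                         sin(angA + k * step))))
}

# planar base template in the pair frame, WCF edge facing +x, major-groove
# exocyclics at +y, glycosidic substituent at -y
.base_xy <- function(base) {
  if (base %in% c("C", "U")) {
    r <- .ring_hex(c("N3", "C4", "C5", "C6", "N1", "C2"))
    at <- rbind(r, O2 = .exo(r, "C2", 1.22))
    at <- rbind(at, if (base == "C") rbind(N4 = .exo(r, "C4", 1.34))
                else rbind(O4 = .exo(r, "C4", 1.22)))
    rbind(at, "C1'" = .exo(r, "N1", 1.47))
  } else {
    r <- .ring_hex(c("N1", "C6", "C5", "C4", "N3", "C2"))
    p5 <- .pent(r, "C4", "C5")
    rownames(p5) <- c("N9", "C8", "N7")
    at <- rbind(r, p5)
    at <- rbind(at, if (base == "A") rbind(N6 = .exo(r, "C6", 1.34))
                else rbind(O6 = .exo(r, "C6", 1.22), N2 = .exo(r, "C2", 1.34)))
    cen5 <- colMeans(at[c("C4", "C5", "N7", "C8", "N9"), ])
    v <- at["N9", ] - cen5
    rbind(at, "C1'" = at["N9", ] + v / sqrt(sum(v^2)) * 1.47)
  }
}

# full residue template (3D, pair frame): strand 2 is the strand-1 frame
# rotated 180 degrees about the y axis and translated across the pair
.residue_xyz <- function(base, strand) {
  xy <- .base_xy(base)
  if (strand == 2L) xy <- cbind(.PAIR_SPAN - xy[, 1], xy[, 2])
  at <- cbind(xy, 0)
  rownames(at) <- rownames(xy)
  capxy <- if (base %in% c("A", "G")) xy["N1", ] else xy["N3", ]
  c1 <- xy["C1'", ]
  u <- c1 - .HELIX_AXIS; u <- u / sqrt(sum(u^2))
  rbind(at,
        "C2'" = c(capxy, -3.0),
        "C5'" = c(capxy, 3.0),
        "C4'" = c(c1 + u * 1.5, 0))
}

# screw transform: rotate by step*twist about the helix axis, rise in z
.helix_place <- function(at, step) {
  th <- step * .TWIST
  rx <- at[, 1] - .HELIX_AXIS[1]; ry <- at[, 2] - .HELIX_AXIS[2]
  out <- cbind(.HELIX_AXIS[1] + rx * cos(th) - ry * sin(th),
               .HELIX_AXIS[2] + rx * sin(th) + ry * cos(th),
               at[, 3] + step * .RISE)
  rownames(out) <- rownames(at)
  out
}

.revcomp <- function(s) paste(rev(unname(.COMP[strsplit(s, "")[[1]]])),
                              collapse = "")

#' Build an idealized A-form RNA model
#'
#' Constructs a duplex (chains A and B, B the reverse complement of
#' `sequence`) or, when `loop` is given, a single-chain hairpin
#' (`sequence` + `loop` + reverse complement of `sequence`).  Helical
#' rise is 2.81 Angstrom and twist 32.7 degrees per step.  Positions
#' listed in `unpaired` are rendered unpaired by omitting the partner
#' residue (a bulge), which leaves the listed base solvent-exposed with
#' zero face hydrogen bonds.  An optional decoy protein chain `P` of
#' alanine-like residues is placed at a controlled minimum distance
#' from a chosen nucleotide.
#'
#' @param sequence strand-1 sequence, 5' to 3' (A/C/G/U).
#' @param loop hairpin loop sequence (empty for a duplex).
#' @param unpaired integer positions of `sequence` to leave unpaired.
#' @param decoy_residues number of decoy-protein residues (0 = none).
#' @param decoy_distance requested minimum atom distance between the
#'   decoy chain and the *target* nucleotide (Angstrom).
#' @param decoy_target strand-1 position the decoy approaches, from the
#'   locally most open direction.  For a terminal target and a contact
#'   cutoff near `decoy_distance` the target is the only contacting
#'   nucleotide; interior targets may bring a neighbour inside the
#'   cutoff as well.
#' @param entry_id accession string stored on the model.
#' @return a `structure_model` with attribute `ground_truth`: data
#'   frame `chain`, `resno`, `base`, `paired` for every nucleotide.
#' @export
build_aform_model <- function(sequence, loop = "", unpaired = integer(0),
                              decoy_residues = 0, decoy_distance = 10,
                              decoy_target = 1L, entry_id = "SYNTH") {
  sequence <- toupper(chartr("T", "U", sequence))
  loop <- toupper(chartr("T", "U", loop))
  s1 <- strsplit(sequence, "")[[1]]
  sl <- if (nzchar(loop)) strsplit(loop, "")[[1]] else character(0)
  if (!all(c(s1, sl) %in% c("A", "C", "G", "U")))
    stop("sequence contains letters other than A/C/G/U", call. = FALSE)
  n <- length(s1)
  if (n < 2) stop("stem must have at least 2 base pairs", call. = FALSE)
  if (length(unpaired) && (any(unpaired < 1) || any(unpaired > n)))
    stop("unpaired positions outside the stem", call. = FALSE)
  hairpin <- length(sl) > 0

  # residue plan: chain/strand/step/base/paired
  plan <- data.frame(strand = 1L, step = seq_len(n) - 1L, base = s1,
                     paired = !(seq_len(n) %in% unpaired),
                     stringsAsFactors = FALSE)
  if (hairpin)
    plan <- rbind(plan,
                  data.frame(strand = 1L, step = n - 1L + seq_along(sl),
                             base = sl, paired = FALSE))
  arm2 <- data.frame(strand = 2L, step = rev(seq_len(n) - 1L),
                     base = unname(.COMP[rev(s1)]),
                     paired = rev(!(seq_len(n) %in% unpaired)),
                     stringsAsFactors = FALSE)
  arm2 <- arm2[arm2$paired, , drop = FALSE]   # bulges: partner omitted
  if (hairpin) {
    plan <- rbind(plan, arm2)
    plan$chain <- "A"
  } else {
    plan$chain <- "A"
    arm2$chain <- "B"
    plan <- rbind(plan, arm2)
  }
  plan$resno <- stats::ave(seq_len(nrow(plan)), plan$chain, FUN = seq_along)

  rows <- lapply(seq_len(nrow(plan)), function(i) {
    tmpl <- .residue_xyz(plan$base[i], plan$strand[i])
    xyz <- .helix_place(tmpl, plan$step[i])
    data.frame(chain = plan$chain[i], resno = plan$resno[i], icode = "",
               resname = plan$base[i], atom = rownames(tmpl),
               element = substr(rownames(tmpl), 1, 1),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               occupancy = 1, altloc = "", stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)

  if (decoy_residues > 0) {
    tgt <- plan[plan$strand == 1L & plan$resno == decoy_target, , drop = FALSE]
    if (nrow(tgt) == 0) stop("decoy_target not found", call. = FALSE)
    # approach from the direction most open around the target: away from
    # the local centroid of every *other* residue's atoms, so the target
    # stays the nearest nucleotide; the requested distance is measured to
    # the target residue's atoms
    is_tgt <- atoms$chain == tgt$chain & atoms$resno == tgt$resno
    anchor <- colMeans(atoms[is_tgt, c("x", "y", "z")])
    others <- as.matrix(atoms[!is_tgt, c("x", "y", "z")])
    near <- others[sqrt(rowSums(sweep(others, 2, anchor)^2)) < 15, ,
                   drop = FALSE]
    dir0 <- anchor - colMeans(near)
    dir0 <- as.numeric(dir0 / sqrt(sum(dir0^2)))
    dec <- .decoy_atoms(decoy_residues)
    tgt_xyz <- as.matrix(atoms[atoms$chain == tgt$chain &
                                 atoms$resno == tgt$resno, c("x", "y", "z")])
    place_at <- function(t) sweep(dec$xyz, 2, anchor + dir0 * t, "+")
    mind <- function(t) min(cpp_cross_pairs(place_at(t), tgt_xyz, 1e6)$dist)
    lo <- 0; hi <- decoy_distance + 40
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (mind(mid) < decoy_distance) lo <- mid else hi <- mid
    }
    xyz <- place_at(hi)
    atoms <- rbind(atoms,
                   data.frame(chain = "P", resno = dec$resno, icode = "",
                              resname = "ALA", atom = dec$atom,
                              element = substr(dec$atom, 1, 1),
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              occupancy = 1, altloc = "",
                              stringsAsFactors = FALSE))
  }

  model <- .structure_model(atoms, entry_id = entry_id)
  truth <- plan[, c("chain", "resno", "base", "paired")]
  ord <- order(truth$chain, truth$resno)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  attr(model, "ground_truth") <- truth
  model
}

# compact alanine-like decoy chain, centred at the origin
.decoy_atoms <- function(n_res) {
  one <- rbind(N = c(0, 0, 0), CA = c(1.46, 0, 0), C = c(2.0, 1.4, 0),
               O = c(3.2, 1.6, 0), CB = c(2.0, -0.9, 1.1))
  xyz <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    sweep(one, 2, c(0, 0, (i - 1) * 3.6), "+")
  }))
  list(xyz = sweep(xyz, 2, colMeans(xyz)),
       atom = rep(rownames(one), n_res),
       resno = rep(seq_len(n_res), each = nrow(one)))
}

# run expr with a fixed RNG state, restoring the caller's state afterwards
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Synthetic study specification
#'
#' Bundles the generator's parameters: geometry of the synthetic
#' duplex, the generative reactivity model, replication and seeding.
#' Per A/C nucleotide the expected reactivity is
#' `mu = max(0, baseline + sasa_coeff * SASA - face_hb_coeff * n_face_hbonds)`
#' and each gene copy observes `mu * exp(eps)` with
#' `eps ~ Normal(0, noise_sd^2)` (multiplicative log-normal noise:
#' probing reactivities are non-negative and right-skewed), dropped to
#' missing with probability `missing_rate`.  G/U positions are missing.
#'
#' @param duplex_length stem length in base pairs.
#' @param n_bulges number of strand-1 positions rendered unpaired.
#' @param loop_length hairpin loop length (0 = duplex).
#' @param baseline,sasa_coeff,face_hb_coeff generative coefficients
#'   (reactivity units; per Angstrom^2; per bond).
#' @param noise_sd log-scale noise standard deviation.
#' @param missing_rate per-position, per-copy missingness probability.
#' @param n_gene_copies number of replicate gene-copy tracks.
#' @param decoy_residues,decoy_distance decoy protein chain size and
#'   minimum distance (Angstrom).
#' @param seed RNG seed; a fixed seed makes all outputs byte-identical.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duplex_length = 540, n_bulges = 80,
                           loop_length = 0,
                           baseline = 0.1, sasa_coeff = 0.05,
                           face_hb_coeff = 0.3, noise_sd = 0.5,
                           missing_rate = 0.05, n_gene_copies = 3,
                           decoy_residues = 0, decoy_distance = 10,
                           seed = 7L) {
  stopifnot(duplex_length >= 4, noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1,
            n_gene_copies >= 1, n_bulges >= 0, n_bulges < duplex_length)
  structure(list(duplex_length = as.integer(duplex_length),
                 n_bulges = as.integer(n_bulges),
                 loop_length = as.integer(loop_length),
                 baseline = baseline, sasa_coeff = sasa_coeff,
                 face_hb_coeff = face_hb_coeff, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 n_gene_copies = as.integer(n_gene_copies),
                 decoy_residues = as.integer(decoy_residues),
                 decoy_distance = decoy_distance,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate the synthetic model described by a spec
#'
#' Draws a random stem sequence and bulge positions from the spec's
#' seed and builds the corresponding model via [build_aform_model()].
#'
#' @param spec a [synthetic_spec()].
#' @return a `structure_model` with `ground_truth` attribute.
#' @export
synthetic_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    s1 <- paste(sample(c("A", "C", "G", "U"), spec$duplex_length,
                       replace = TRUE), collapse = "")
    bulge <- if (spec$n_bulges > 0)
      sort(sample(seq_len(spec$duplex_length), spec$n_bulges)) else integer(0)
    loop <- if (spec$loop_length > 0)
      paste(sample(c("A", "C", "G", "U"), spec$loop_length, replace = TRUE),
            collapse = "") else ""
    build_aform_model(s1, loop = loop, unpaired = bulge,
                      decoy_residues = spec$decoy_residues,
                      decoy_distance = spec$decoy_distance,
                      entry_id = sprintf("SYN%04d", spec$seed %% 10000L))
  })
}

#' Simulate reactivity tracks from structural features
#'
#' Applies the generative model of [synthetic_spec()] to the computed
#' features of a chain: expected reactivity rises with reactive-atom
#' SASA and falls with the WCF-face hydrogen-bond count, replicate
#' gene-copy tracks share the expectation and draw independent noise
#' and missingness.
#'
#' @param model a `structure_model`.
#' @param chain chain identifier the tracks describe.
#' @param sasa result of [shrake_rupley()] on the model.
#' @param bonds result of [detect_hbonds()] on the model.
#' @param spec a [synthetic_spec()].
#' @return list with `tracks` (a `react_set`, one track per gene copy,
#'   ids `"101"`, `"102"`, ...) and `mu` (the per-position expected
#'   reactivity, `NA` at G/U positions).
#' @export
simulate_reactivity <- function(model, chain, sasa, bonds, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  res <- model$residues[model$residues$chain == chain, , drop = FALSE]
  n <- nrow(res)
  rsasa <- reactive_sasa(model, sasa, chains = chain)
  cnt <- .hb_count_table(model, bonds)
  mu <- rep(NA_real_, n)
  idx <- match(rsasa$res_uid, res$res_uid)
  hb <- cnt$n_hb_face[match(rsasa$res_uid, cnt$res_uid)]
  mu[idx] <- pmax(0, spec$baseline + spec$sasa_coeff * rsasa$sasa -
                    spec$face_hb_coeff * hb)
  tracks <- .with_seed(spec$seed + 1L, {
    lapply(seq_len(spec$n_gene_copies), function(k) {
      v <- mu * exp(stats::rnorm(n, 0, spec$noise_sd))
      drop <- stats::runif(n) < spec$missing_rate
      v[drop] <- NA_real_
      v
    })
  })
  names(tracks) <- as.character(100L + seq_len(spec$n_gene_copies))
  class(tracks) <- "react_set"
  list(tracks = tracks, mu = mu)
}

#' Write a complete synthetic fixture set
#'
#' Emits, deterministically from the spec's seed: the model as PDB
#' (`model.pdb`), simulated tracks as `.react` text
#' (`reactivity.react`), and ground-truth labels as TSV (`truth.tsv`).
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir writable output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_fixtures <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- synthetic_model(spec)
  sasa <- shrake_rupley(model)
  bonds <- detect_hbonds(model)
  sim <- simulate_reactivity(model, "A", sasa, bonds, spec)
  paths <- c(model = file.path(out_dir, "model.pdb"),
             react = file.path(out_dir, "reactivity.react"),
             truth = file.path(out_dir, "truth.tsv"))
  write_pdb(model, paths["model"])
  write_react(sim$tracks, paths["react"])
  truth <- attr(model, "ground_truth")
  truth$mu <- NA_real_
  ca <- truth$chain == "A"
  truth$mu[ca] <- sim$mu[match(truth$resno[ca],
                               seq_along(sim$mu))]
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
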