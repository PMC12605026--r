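# hydrogen bonds -------------------------------------------------------------

# Watson-Crick-Franklin edge atoms per base, used for base-pair detection
.WCF_EDGE <- list(A = c("N1", "N6"),
                  G = c("N1", "N2", "O6"),
                  C = c("N3", "N4", "O2"),
                  U = c("N3", "O2", "O4"))

# atoms counted as "at/near the WCF face" for the H-bond ROC feature;
# the sugar-edge N3 of adenosine is included deliberately
.FACE_ROC <- list(A = c("N6", "N1", "N3"),
                  C = c("N4", "N3", "O2"))

#' Detect hydrogen bonds by heteroatom distance
#'
#' A hydrogen bond is recorded for every nitrogen/oxygen pair of
#' different residues at a distance between `d_min` and `d_max`
#' (default 2.0-3.5 Angstrom), the criterion usable on models without
#' hydrogens.  Covalently linked inter-residue pairs are excluded:
#' the nucleic-acid backbone bridge (O3' of residue i against the
#' phosphate oxygens O5'/OP1/OP2/OP3 of residue i+1) and the peptide
#' carbonyl-amide pair (O of residue i against N of residue i+1).
#' Waters and free ions are excluded by default.
#'
#' @param model a `structure_model`.
#' @param d_min,d_max distance window in Angstrom.
#' @param include_solvent include water/ion residues as partners.
#' @return data frame of class `hbond_set`, one row per unordered bond,
#'   deterministically ordered; columns `res_uid_a`, `chain_a`,
#'   `resno_a`, `icode_a`, `resname_a`, `atom_a`, the same for `b`
#'   (`res_uid_a < res_uid_b`), and `dist`.
#' @export
detect_hbonds <- function(model, d_min = 2.0, d_max = 3.5,
                          include_solvent = FALSE) {
  stopifnot(inherits(model, "structure_model"), d_min > 0, d_max >= d_min)
  at <- model$atoms
  keep <- at$element %in% c("N", "O")
  if (!include_solvent) {
    solv <- model$residues$res_uid[model$residues$kind == "other" &
                                     toupper(model$residues$resname) %in% .SOLVENT]
    keep <- keep & !(at$res_uid %in% solv)
  }
  at <- at[keep, , drop = FALSE]
  empty <- data.frame(res_uid_a = integer(), chain_a = character(),
                      resno_a = integer(), icode_a = character(),
                      resname_a = character(), atom_a = character(),
                      res_uid_b = integer(), chain_b = character(),
                      resno_b = integer(), icode_b = character(),
                      resname_b = character(), atom_b = character(),
                      dist = numeric(), stringsAsFactors = FALSE)
  if (nrow(at) < 2) return(structure(empty, class = c("hbond_set", "data.frame")))

  pr <- cpp_close_pairs(as.matrix(at[, c("x", "y", "z")]), d_max)
  pr <- pr[pr$dist >= d_min, , drop = FALSE]
  ua <- at$res_uid[pr$i]; ub <- at$res_uid[pr$j]
  pr <- pr[ua != ub, , drop = FALSE]
  if (nrow(pr) == 0) return(structure(empty, class = c("hbond_set", "data.frame")))

  # orient each pair so residue a precedes residue b
  ua <- at$res_uid[pr$i]; ub <- at$res_uid[pr$j]
  flip <- ua > ub
  i1 <- ifelse(flip, pr$j, pr$i); i2 <- ifelse(flip, pr$i, pr$j)

  # covalent-adjacency exclusion: consecutive residues of the same chain
  # with contiguous author numbering (a numbering gap means a chain break)
  adj <- at$chain[i1] == at$chain[i2] &
    (at$res_uid[i2] - at$res_uid[i1]) == 1L &
    (at$resno[i2] - at$resno[i1]) <= 1L
  a1 <- at$atom[i1]; a2 <- at$atom[i2]
  bridge <- adj & ((a1 == "O3'" & a2 %in% c("O5'", "OP1", "OP2", "OP3")) |
                     (a1 == "O" & a2 == "N"))
  pr <- pr[!bridge, , drop = FALSE]; i1 <- i1[!bridge]; i2 <- i2[!bridge]
  if (length(i1) == 0) return(structure(empty, class = c("hbond_set", "data.frame")))

  out <- data.frame(res_uid_a = at$res_uid[i1], chain_a = at$chain[i1],
                    resno_a = at$resno[i1], icode_a = at$icode[i1],
                    resname_a = at$resname[i1], atom_a = at$atom[i1],
                    res_uid_b = at$res_uid[i2], chain_b = at$chain[i2],
                    resno_b = at$resno[i2], icode_b = at$icode[i2],
                    resname_b = at$resname[i2], atom_b = at$atom[i2],
                    dist = pr$dist, stringsAsFactors = FALSE)
  out <- out[order(out$res_uid_a, out$atom_a, out$res_uid_b, out$atom_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hbond_set", "data.frame"))
}

# residue lookup: (chain, resno, icode) -> res_uid, or error
.res_uid <- function(model, chain, resno, icode = "") {
  hit <- model$residues$chain == chain & model$residues$resno == resno &
    model$residues$icode == icode
  if (!any(hit))
    stop("no residue ", chain, ":", resno, icode, " in model", call. = FALSE)
  model$residues$res_uid[hit][1]
}

#' Count hydrogen bonds to any atom of a residue
#'
#' Counts bond records incident to any atom (base, sugar or phosphate)
#' of the residue.
#'
#' @param model a `structure_model`.
#' @param bonds result of [detect_hbonds()] on the same model.
#' @param chain,resno,icode residue identifier.
#' @return integer count.
#' @export
count_hbonds_any <- function(model, bonds, chain, resno, icode = "") {
  uid <- .res_uid(model, chain, resno, icode)
  sum(bonds$res_uid_a == uid) + sum(bonds$res_uid_b == uid)
}

#' Count hydrogen bonds at/near the WCF face of an A or C
#'
#' Counts bonds incident to N6/N1/N3 of adenosine or N4/N3/O2 of
#' cytosine (modified nucleosides follow their parent base).  The N3 of
#' adenosine sits on the sugar edge but is included: occupancy there
#' also protects the base from methylation.
#'
#' @inheritParams count_hbonds_any
#' @return integer count.
#' @export
count_wcf_face_hbonds <- function(model, bonds, chain, resno, icode = "") {
  uid <- .res_uid(model, chain, resno, icode)
  base <- model$residues$base[model$residues$res_uid == uid]
  if (is.na(base) || !base %in% c("A", "C"))
    stop("residue ", chain, ":", resno, icode,
         " is not an adenosine or cytidine", call. = FALSE)
  face <- .FACE_ROC[[base]]
  sum(bonds$res_uid_a == uid & bonds$atom_a %in% face) +
    sum(bonds$res_uid_b == uid & bonds$atom_b %in% face)
}

# vectorized counts for all residues: data frame res_uid, n_hb_any, n_hb_face
.hb_count_table <- function(model, bonds) {
  res <- model$residues
  tab_any <- table(factor(c(bonds$res_uid_a, bonds$res_uid_b),
                          levels = res$res_uid))
  face_a <- mapply(function(uid, atom) {
    b <- res$base[uid]
    !is.na(b) && b %in% names(.FACE_ROC) && atom %in% .FACE_ROC[[b]]
  }, bonds$res_uid_a, bonds$atom_a, USE.NAMES = FALSE)
  face_b <- mapply(function(uid, atom) {
    b <- res$base[uid]
    !is.na(b) && b %in% names(.FACE_ROC) && atom %in% .FACE_ROC[[b]]
  }, bonds$res_uid_b, bonds$atom_b, USE.NAMES = FALSE)
  uids <- c(bonds$res_uid_a[as.logical(face_a)],
            bonds$res_uid_b[as.logical(face_b)])
  tab_face <- table(factor(uids, levels = res$res_uid))
  data.frame(res_uid = res$res_uid,
             n_hb_any = as.integer(tab_any),
             n_hb_face = as.integer(tab_face))
}

# base pairs ------------------------------------------------------------------

#' Annotate canonical Watson-Crick-Franklin base pairs
#'
#' A residue pair is annotated `canonical_wcf` when the bases are
#' complementary (A-U or G-C; G-U wobbles are classified `other`),
#' at least two hydrogen bonds connect their WCF edges, the C1'-C1'
#' distance lies within 10.4 +/- 1.5 Angstrom, and the residues are
#' either on different chains or separated by at least two positions in
#' the chain.  Pairs of nucleotides joined by >= 2 WCF-edge bonds that
#' fail the complementarity test are reported as class `other`.
#'
#' @param model a `structure_model`.
#' @param bonds result of [detect_hbonds()].
#' @param c1_window centre and half-width of the accepted C1'-C1'
#'   distance window in Angstrom.
#' @return data frame of class `basepair_set`: one row per pair with
#'   residue keys for `i` and `j` (`res_uid_i < res_uid_j`),
#'   `pair_class` and `n_face_hbonds`, plus attribute `paired`: a
#'   logical vector over `model$residues` (TRUE iff the nucleotide is a
#'   member of at least one canonical pair), retrievable with
#'   [paired_flags()].
#' @export
annotate_base_pairs <- function(model, bonds, c1_window = c(10.4, 1.5)) {
  stopifnot(inherits(model, "structure_model"))
  res <- model$residues
  base_a <- res$base[bonds$res_uid_a]
  base_b <- res$base[bonds$res_uid_b]
  edge <- function(base, atom) {
    if (length(atom) == 0) return(logical(0))
    ok <- !is.na(base) & base %in% names(.WCF_EDGE)
    ok & mapply(function(b, a) a %in% .WCF_EDGE[[b]],
                ifelse(ok, base, "A"), atom)
  }
  ff <- edge(base_a, bonds$atom_a) & edge(base_b, bonds$atom_b)
  cand <- bonds[ff, , drop = FALSE]

  out <- data.frame(res_uid_i = integer(), res_uid_j = integer(),
                    pair_class = character(), n_face_hbonds = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(cand)) {
    key <- paste(cand$res_uid_a, cand$res_uid_b)
    n_ff <- table(key)
    uid_i <- as.integer(sub(" .*", "", names(n_ff)))
    uid_j <- as.integer(sub(".* ", "", names(n_ff)))
    keep <- as.integer(n_ff) >= 2L

    # chain/sequence separation: same chain requires |i - j| >= 2 in
    # residue order (res_uid is consecutive within a chain)
    same_chain <- res$chain[uid_i] == res$chain[uid_j]
    keep <- keep & (!same_chain | abs(uid_i - uid_j) >= 2L)

    # C1'-C1' window
    at <- model$atoms
    c1 <- at[at$atom == "C1'", , drop = FALSE]
    c1i <- match(uid_i, c1$res_uid); c1j <- match(uid_j, c1$res_uid)
    d_c1 <- sqrt((c1$x[c1i] - c1$x[c1j])^2 + (c1$y[c1i] - c1$y[c1j])^2 +
                   (c1$z[c1i] - c1$z[c1j])^2)
    keep <- keep & !is.na(d_c1) &
      abs(d_c1 - c1_window[1]) <= c1_window[2]

    comp <- paste(res$base[uid_i], res$base[uid_j])
    canonical <- comp %in% c("A U", "U A", "G C", "C G")
    out <- data.frame(res_uid_i = uid_i[keep], res_uid_j = uid_j[keep],
                      pair_class = ifelse(canonical[keep], "canonical_wcf",
                                          "other"),
                      n_face_hbonds = as.integer(n_ff)[keep],
                      stringsAsFactors = FALSE)
    out <- out[order(out$res_uid_i, out$res_uid_j), , drop = FALSE]
  }
  ki <- match(out$res_uid_i, res$res_uid); kj <- match(out$res_uid_j, res$res_uid)
  out <- cbind(out[, c("res_uid_i", "res_uid_j")],
               chain_i = res$chain[ki], resno_i = res$resno[ki],
               name_i = res$resname[ki],
               chain_j = res$chain[kj], resno_j = res$resno[kj],
               name_j = res$resname[kj],
               out[, c("pair_class", "n_face_hbonds")])
  rownames(out) <- NULL
  paired <- res$res_uid %in% c(out$res_uid_i[out$pair_class == "canonical_wcf"],
                               out$res_uid_j[out$pair_class == "canonical_wcf"])
  attr(out, "paired") <- paired
  structure(out, class = c("basepair_set", "data.frame"))
}

#' Per-nucleotide paired/unpaired flags
#'
#' @param model a `structure_model`.
#' @param pairs result of [annotate_base_pairs()].
#' @return data frame `res_uid`, `paired` over all residues of the model.
#' @export
paired_flags <- function(model, pairs) {
  data.frame(res_uid = model$residues$res_uid, paired = attr(pairs, "paired"))
}

# protein-RNA contacts --------------------------------------------------------

#' Count protein-RNA atom contacts
#'
#' For a set of nucleotides, counts the (RNA atom, protein atom) pairs
#' within `cutoff` for each protein chain.  Counting is per atom pair,
#' not per residue; a chain is reported only if it has at least one
#' qualifying pair.
#'
#' @param model a `structure_model`.
#' @param nucleotides data frame with columns `chain`, `resno` and
#'   optionally `icode` selecting the RNA residues of interest.
#' @param cutoff contact distance in Angstrom (default 4.0).
#' @return data frame of class `contact_table`: `protein_chain`,
#'   `n_atom_contacts`, `nucleotides` (comma-separated contributing
#'   residues as `chain:resno`).
#' @export
protein_rna_contacts <- function(model, nucleotides, cutoff = 4.0) {
  stopifnot(inherits(model, "structure_model"))
  empty <- structure(data.frame(protein_chain = character(),
                                n_atom_contacts = integer(),
                                nucleotides = character(),
                                stringsAsFactors = FALSE),
                     class = c("contact_table", "data.frame"))
  if (is.null(nucleotides) || nrow(nucleotides) == 0) return(empty)
  if (is.null(nucleotides$icode)) nucleotides$icode <- ""
  uids <- mapply(.res_uid, nucleotides$chain, nucleotides$resno,
                 nucleotides$icode, MoreArgs = list(model = model))
  res <- model$residues
  bad <- model$chain_kind[res$chain[match(uids, res$res_uid)]] != "rna"
  if (any(bad))
    stop("nucleotide selection includes residues outside RNA chains",
         call. = FALSE)
  at <- model$atoms
  rna <- at[at$res_uid %in% uids, , drop = FALSE]
  prot_chains <- names(model$chain_kind)[model$chain_kind == "protein"]
  prot <- at[at$chain %in% prot_chains, , drop = FALSE]
  if (nrow(rna) == 0 || nrow(prot) == 0) return(empty)
  pr <- cpp_cross_pairs(as.matrix(rna[, c("x", "y", "z")]),
                        as.matrix(prot[, c("x", "y", "z")]), cutoff)
  if (nrow(pr) == 0) return(empty)
  pchain <- prot$chain[pr$j]
  nt_lab <- paste0(rna$chain[pr$i], ":", rna$resno[pr$i],
                   ifelse(nzchar(rna$icode[pr$i]), rna$icode[pr$i], ""))
  out <- do.call(rbind, lapply(split(seq_along(pchain), pchain), function(k) {
    data.frame(protein_chain = pchain[k[1]],
               n_atom_contacts = length(k),
               nucleotides = paste(sort(unique(nt_lab[k])), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$protein_chain), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("contact_table", "data.frame"))
}

#' Average two contact tables across conditions
#'
#' Arithmetic mean of per-chain atom-contact counts from two structures
#' (e.g. two growth conditions), rounded to the nearest integer; chains
#' absent from one table contribute a zero there.
#'
#' @param a,b `contact_table` objects.
#' @return data frame `protein_chain`, `n_atom_contacts` (rounded mean).
#' @export
average_contacts <- function(a, b) {
  chains <- sort(unique(c(a$protein_chain, b$protein_chain)))
  ca <- a$n_atom_contacts[match(chains, a$protein_chain)]
  cb <- b$n_atom_contacts[match(chains, b$protein_chain)]
  ca[is.na(ca)] <- 0L; cb[is.na(cb)] <- 0L
  data.frame(protein_chain = chains,
             n_atom_contacts = as.integer(round((ca + cb) / 2)),
             stringsAsFactors = FALSE)
}

# superposition ---------------------------------------------------------------

#' Rigid-body superposition and RMSD
#'
#' Least-squares superposition of matched atoms by the standard SVD
#' (Kabsch) construction with reflection guard, followed by global and
#' per-residue root-mean-square deviation over the mapped atoms.
#'
#' @param model_a,model_b `structure_model` objects.
#' @param selection optional data frame pairing atoms: columns
#'   `chain_a`, `resno_a`, `icode_a`, `atom_a` and the `_b`
#'   counterparts.  By default, atoms with identical
#'   (chain, resno, icode, atom) keys present in both models are paired.
#' @return list with `rmsd` (global, Angstrom), `per_residue` (data
#'   frame keyed by model-a residues), `rotation` (3x3), `translation`
#'   (length 3, applied to model b after rotation about its centroid),
#'   and `n` (atom pairs used).
#' @export
superpose_rmsd <- function(model_a, model_b, selection = NULL) {
  stopifnot(inherits(model_a, "structure_model"),
            inherits(model_b, "structure_model"))
  ata <- model_a$atoms; atb <- model_b$atoms
  if (is.null(selection)) {
    ka <- paste(ata$chain, ata$resno, ata$icode, ata$atom, sep = "\r")
    kb <- paste(atb$chain, atb$resno, atb$icode, atb$atom, sep = "\r")
    common <- intersect(ka, kb)
    ia <- match(common, ka); ib <- match(common, kb)
  } else {
    if (is.null(selection$icode_a)) selection$icode_a <- ""
    if (is.null(selection$icode_b)) selection$icode_b <- ""
    ka <- paste(ata$chain, ata$resno, ata$icode, ata$atom, sep = "\r")
    kb <- paste(atb$chain, atb$resno, atb$icode, atb$atom, sep = "\r")
    ia <- match(paste(selection$chain_a, selection$resno_a,
                      selection$icode_a, selection$atom_a, sep = "\r"), ka)
    ib <- match(paste(selection$chain_b, selection$resno_b,
                      selection$icode_b, selection$atom_b, sep = "\r"), kb)
    if (anyNA(ia) || anyNA(ib))
      stop("selection names atoms absent from the models", call. = FALSE)
  }
  A <- as.matrix(ata[ia, c("x", "y", "z")])
  B <- as.matrix(atb[ib, c("x", "y", "z")])
  n <- nrow(A)
  if (n < 3) stop("degenerate selection: fewer than 3 atom pairs", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv_chk <- svd(A0)$d
  if (sv_chk[2] < 1e-8 * max(sv_chk[1], 1))
    stop("degenerate selection: mapped atoms are collinear", call. = FALSE)
  H <- crossprod(B0, A0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Bfit <- B0 %*% t(R)
  dev2 <- rowSums((A0 - Bfit)^2)
  rmsd <- sqrt(mean(dev2))
  uid <- ata$res_uid[ia]
  per <- vapply(split(dev2, uid), function(v) sqrt(mean(v)), 0)
  ridx <- match(as.integer(names(per)), model_a$residues$res_uid)
  per_residue <- data.frame(chain = model_a$residues$chain[ridx],
                            resno = model_a$residues$resno[ridx],
                            icode = model_a$residues$icode[ridx],
                            rmsd = unname(per), stringsAsFactors = FALSE)
  list(rmsd = rmsd, per_residue = per_residue, rotation = R,
       translation = ca - cb %*% t(R), n = n)
}
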