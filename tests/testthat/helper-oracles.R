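# Independent oracles and fixture builders shared across the suite.
# Every oracle here deliberately avoids the package's own code paths:
# Monte-Carlo point sampling instead of the Fibonacci lattice, full
# distance matrices instead of the grid search, exhaustive pair counts
# instead of the threshold sweep.

.VDW <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)

# Monte-Carlo SASA for selected atom indices of a structure_model
mc_sasa_oracle <- function(model, idx, probe = 1.4, npts = 20000) {
  at <- model$atoms
  co <- as.matrix(at[, c("x", "y", "z")])
  r <- unname(.VDW[at$element]) + probe
  vapply(idx, function(i) {
    u <- matrix(rnorm(3 * npts), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * r[i], 2, co[i, ], "+")
    free <- rep(TRUE, npts)
    for (j in seq_len(nrow(co))) {
      if (j == i) next
      dd <- sqrt(colSums((t(pts) - co[j, ])^2))
      free <- free & (dd >= r[j])
    }
    mean(free) * 4 * pi * r[i]^2
  }, 0)
}

# brute-force all-pairs H-bond scan with the same stated exclusion rules
brute_hbonds <- function(model, d_min = 2.0, d_max = 3.5) {
  at <- model$atoms
  solv <- model$residues$res_uid[model$residues$kind == "other"]
  at <- at[at$element %in% c("N", "O") & !(at$res_uid %in% solv), ]
  n <- nrow(at)
  out <- NULL
  if (n >= 2) {
    dm <- as.matrix(dist(at[, c("x", "y", "z")]))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (at$res_uid[i] == at$res_uid[j]) next
      d <- dm[i, j]
      if (d < d_min || d > d_max) next
      a <- if (at$res_uid[i] < at$res_uid[j]) i else j
      b <- if (at$res_uid[i] < at$res_uid[j]) j else i
      adj <- at$chain[a] == at$chain[b] && at$res_uid[b] - at$res_uid[a] == 1
      if (adj && ((at$atom[a] == "O3'" &&
                     at$atom[b] %in% c("O5'", "OP1", "OP2", "OP3")) ||
                    (at$atom[a] == "O" && at$atom[b] == "N"))) next
      out <- rbind(out, data.frame(res_uid_a = at$res_uid[a],
                                   atom_a = at$atom[a],
                                   res_uid_b = at$res_uid[b],
                                   atom_b = at$atom[b], dist = d))
    }
  }
  if (is.null(out)) out <- data.frame(res_uid_a = integer(), atom_a = character(),
                                      res_uid_b = integer(), atom_b = character(),
                                      dist = numeric())
  out[order(out$res_uid_a, out$atom_a, out$res_uid_b, out$atom_b), ]
}

# exhaustive pairwise Mann-Whitney AUC: P(pos > neg) + P(tie)/2
pair_auc_oracle <- function(labels, scores) {
  sp <- scores[labels]; sn <- scores[!labels]
  g <- expand.grid(p = sp, n = sn)
  mean((g$p > g$n) + 0.5 * (g$p == g$n))
}

# expected AUC of the log-normal generative model, per positive/negative
# pair of expected reactivities
expected_auc_oracle <- function(mu_pos, mu_neg, noise_sd) {
  g <- expand.grid(p = mu_pos, n = mu_neg)
  if (noise_sd > 0) {
    mean(ifelse(g$p > 0 & g$n > 0,
                pnorm(log(g$p / g$n) / (noise_sd * sqrt(2))),
                ifelse(g$p > 0 & g$n == 0, 1,
                       ifelse(g$p == 0 & g$n > 0, 0, 0.5))))
  } else {
    mean((g$p > g$n) + 0.5 * (g$p == g$n))
  }
}

# write a hand-constructed PDB file from an atom table
write_pdb_text <- function(df, path = tempfile(fileext = ".pdb")) {
  if (is.null(df$icode)) df$icode <- ""
  if (is.null(df$occ)) df$occ <- 1
  if (is.null(df$alt)) df$alt <- ""
  lines <- vapply(seq_len(nrow(df)), function(i) {
    nm <- df$atom[i]
    nm4 <- if (nchar(nm) <= 3) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, nm4, ifelse(nzchar(df$alt[i]), df$alt[i], " "),
            df$resname[i], df$chain[i], df$resno[i],
            ifelse(nzchar(df$icode[i]), df$icode[i], " "),
            df$x[i], df$y[i], df$z[i], df$occ[i], 0, df$element[i])
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

# the same atom table serialized as minimal mmCIF
write_cif_text <- function(df, path = tempfile(fileext = ".cif")) {
  if (is.null(df$occ)) df$occ <- 1
  hdr <- c("data_TEST", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  rows <- vapply(seq_len(nrow(df)), function(i) {
    paste("ATOM", i, df$element[i], df$atom[i], ".", df$resname[i],
          df$chain[i], 1, df$resno[i], "?",
          sprintf("%.3f %.3f %.3f", df$x[i], df$y[i], df$z[i]),
          sprintf("%.2f", df$occ[i]), "0.00", df$resno[i], df$resname[i],
          df$chain[i], df$atom[i], 1)
  }, "")
  writeLines(c(hdr, rows, "#"), path)
  path
}

# shared small synthetic study, computed once per test run
.study_cache <- new.env(parent = emptyenv())
small_study <- function() {
  if (!is.null(.study_cache$s)) return(.study_cache$s)
  spec <- synthetic_spec(duplex_length = 40, n_bulges = 8, seed = 11,
                         missing_rate = 0.05)
  model <- synthetic_model(spec)
  sasa <- shrake_rupley(model)
  bonds <- detect_hbonds(model)
  pairs <- annotate_base_pairs(model, bonds)
  sim <- simulate_reactivity(model, "A", sasa, bonds, spec)
  avg <- average_gene_copies(sim$tracks, names(sim$tracks))
  cs <- chain_sequence(model, "A")
  map <- build_numbering_map(cs$sequence, cs$sequence, cs$keys)
  ft <- build_feature_table(model, sasa, bonds, pairs, map, avg)
  .study_cache$s <- list(spec = spec, model = model, sasa = sasa,
                         bonds = bonds, pairs = pairs, sim = sim, avg = avg,
                         map = map, ft = ft)
  .study_cache$s
}
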