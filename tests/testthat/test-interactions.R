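test_that("distance window bounds are respected", {
  mk <- function(d) read_structure(write_pdb_text(
    data.frame(chain = "A", resno = c(1, 3), resname = "A", atom = "N1",
               element = c("O", "O"), x = c(0, d), y = 0, z = 0)))
  expect_equal(nrow(detect_hbonds(mk(3.6))), 0L)
  expect_equal(nrow(detect_hbonds(mk(3.4))), 1L)
  expect_equal(nrow(detect_hbonds(mk(1.9))), 0L)
  expect_equal(nrow(detect_hbonds(mk(2.0))), 1L)
})

test_that("an idealized A-U pair gives exactly the two canonical bonds", {
  m <- build_aform_model("AA")
  b <- detect_hbonds(m)
  b12 <- b[b$chain_a == "A" & b$resno_a == 1, ]
  expect_setequal(paste(b12$atom_a, b12$atom_b),
                  c("N1 N3", "N6 O4"))
  expect_true(all(b$dist >= 2 & b$dist <= 3.5))
})

test_that("detection equals the brute-force all-pairs oracle on fixtures", {
  fixtures <- list(
    small_study()$model,
    build_aform_model("GGAC", loop = "GAAC"),
    build_aform_model("AUGCAU", unpaired = 3, decoy_residues = 2,
                      decoy_distance = 3.2))
  for (m in fixtures) {
    got <- detect_hbonds(m)
    ref <- brute_hbonds(m)
    expect_equal(nrow(got), nrow(ref))
    expect_equal(got$res_uid_a, ref$res_uid_a)
    expect_equal(got$atom_a, ref$atom_a)
    expect_equal(got$res_uid_b, ref$res_uid_b)
    expect_equal(got$atom_b, ref$atom_b)
    expect_equal(got$dist, ref$dist, tolerance = 1e-12)
  }
})

test_that("the backbone bridge O3'-O5' pair is excluded as covalent", {
  df <- data.frame(chain = "A", resno = c(1, 2), resname = c("A", "G"),
                   atom = c("O3'", "O5'"), element = "O",
                   x = c(0, 2.4), y = 0, z = 0)
  m <- read_structure(write_pdb_text(df))
  expect_equal(nrow(detect_hbonds(m)), 0L)
  # the same pair across non-consecutive residues is a real contact
  df$resno <- c(1, 5)
  m <- read_structure(write_pdb_text(df))
  expect_equal(nrow(detect_hbonds(m)), 1L)
})

test_that("any-atom counts satisfy the handshake identity", {
  s <- small_study()
  res <- s$model$residues
  counts <- vapply(seq_len(nrow(res)), function(i)
    count_hbonds_any(s$model, s$bonds, res$chain[i], res$resno[i],
                     res$icode[i]), 0L)
  expect_equal(sum(counts), 2L * nrow(s$bonds))
  expect_equal(unname(counts[1]),
               count_hbonds_any(s$model, s$bonds, res$chain[1], res$resno[1]))
})

test_that("an interior G-C pair carries three bonds on the C", {
  m <- build_aform_model("AGCA")
  b <- detect_hbonds(m)
  expect_gte(count_hbonds_any(m, b, "A", 3), 3L)     # the C of G-C
  expect_equal(count_wcf_face_hbonds(m, b, "A", 3), 3L)
})

test_that("face counts: paired A has 2, bulged bases have 0, G/U error", {
  m <- build_aform_model("UACGU", unpaired = 2)
  b <- detect_hbonds(m)
  expect_equal(count_wcf_face_hbonds(m, b, "A", 3), 3L)  # paired C
  expect_equal(count_wcf_face_hbonds(m, b, "A", 2), 0L)  # bulged A
  m2 <- build_aform_model("UAAGU")
  b2 <- detect_hbonds(m2)
  expect_equal(count_wcf_face_hbonds(m2, b2, "A", 2), 2L)  # paired A: N1+N6
  expect_error(count_wcf_face_hbonds(m2, b2, "A", 1), "adenosine or cytidine")
})

test_that("a sugar-side contact does not touch the face atoms of C", {
  # lone N parked next to the C1'/sugar carbons of a bulged C, far from
  # its N3/N4/O2 face
  m <- build_aform_model("GCG", unpaired = 2)
  at <- m$atoms
  sel <- at$resno == 2 & at$chain == "A"
  bc <- colMeans(at[sel & at$atom %in% c("N3", "C4", "C5", "C6", "N1", "C2"),
                    c("x", "y", "z")])
  c4 <- unlist(at[sel & at$atom == "C4'", c("x", "y", "z")])
  u <- (c4 - bc) / sqrt(sum((c4 - bc)^2))
  probe <- c4 + 3 * u       # beyond the sugar carbon, away from the base
  face <- at[at$resno == 2 & at$chain == "A" &
               at$atom %in% c("N3", "N4", "O2"), c("x", "y", "z")]
  stopifnot(min(sqrt(colSums((t(face) - probe)^2))) > 3.5)
  df <- data.frame(chain = at$chain, resno = at$resno, resname = at$resname,
                   atom = at$atom, element = at$element,
                   x = at$x, y = at$y, z = at$z)
  df <- rbind(df, data.frame(chain = "X", resno = 99, resname = "A",
                             atom = "N1", element = "N",
                             x = probe[1], y = probe[2], z = probe[3]))
  m2 <- read_structure(write_pdb_text(df))
  b <- detect_hbonds(m2)
  expect_equal(count_wcf_face_hbonds(m2, b, "A", 2), 0L)
})

test_that("duplex interiors pair and hairpin loops do not", {
  m <- build_aform_model("GAUCGCAUCGGC")
  p <- annotate_base_pairs(m, detect_hbonds(m))
  expect_equal(sum(p$pair_class == "canonical_wcf"), 12L)
  fl <- paired_flags(m, p)
  expect_true(all(fl$paired))

  h <- build_aform_model("GGCACG", loop = "UUCG")
  ph <- annotate_base_pairs(h, detect_hbonds(h))
  flh <- paired_flags(h, ph)
  expect_true(all(flh$paired[1:6]))
  expect_false(any(flh$paired[7:10]))
  expect_true(all(flh$paired[11:16]))
})

test_that("a distant complementary base is not a pair", {
  df <- rbind(
    data.frame(chain = "A", resno = 1, resname = "A",
               atom = c("N1", "N6", "C1'"), element = c("N", "N", "C"),
               x = c(0, 1, -2), y = c(0, 2, -2), z = 0),
    data.frame(chain = "B", resno = 1, resname = "U",
               atom = c("N3", "O4", "C1'"), element = c("N", "O", "C"),
               x = c(15, 16, 17), y = c(0, 2, -2), z = 0))
  m <- read_structure(write_pdb_text(df))
  p <- annotate_base_pairs(m, detect_hbonds(m))
  expect_equal(nrow(p), 0L)
  expect_false(any(attr(p, "paired")))
})

test_that("a G-U wobble with two edge bonds is classified other", {
  df <- rbind(
    data.frame(chain = "X", resno = 1, resname = "G",
               atom = c("N1", "O6", "C1'"), element = c("N", "O", "C"),
               x = c(0, 0, -4.4), y = c(0, 2.2, 1), z = 0),
    data.frame(chain = "Y", resno = 1, resname = "U",
               atom = c("O2", "N3", "C1'"), element = c("O", "N", "C"),
               x = c(2.85, 2.85, 5.9), y = c(0, 2.2, 1), z = 0))
  m <- read_structure(write_pdb_text(df))
  p <- annotate_base_pairs(m, detect_hbonds(m))
  expect_equal(nrow(p), 1L)
  expect_equal(p$pair_class, "other")
  expect_false(any(attr(p, "paired")))
})

test_that("pairing requires >= 2 WCF-face bonds by construction", {
  s <- small_study()
  p <- s$pairs
  canon <- p[p$pair_class == "canonical_wcf", ]
  expect_true(all(canon$n_face_hbonds >= 2))
})

test_that("contact counting matches an exhaustive distance oracle", {
  m <- build_aform_model("GCAUGC", decoy_residues = 3, decoy_distance = 3.0,
                         decoy_target = 1)
  nts <- data.frame(chain = "A", resno = 1:6)
  ct <- protein_rna_contacts(m, nts, cutoff = 4.0)
  # brute force
  at <- m$atoms
  rna <- at[at$chain %in% c("A") & at$resno %in% 1:6, ]
  prot <- at[at$chain == "P", ]
  dm <- as.matrix(dist(rbind(rna[, c("x", "y", "z")],
                             prot[, c("x", "y", "z")])))
  dd <- dm[seq_len(nrow(rna)), nrow(rna) + seq_len(nrow(prot))]
  expect_equal(ct$n_atom_contacts, sum(dd <= 4.0))
  expect_gte(ct$n_atom_contacts, 1L)
})

test_that("a decoy 10 A away produces an empty contact table", {
  m <- build_aform_model("GCAUGC", decoy_residues = 2, decoy_distance = 10)
  ct <- protein_rna_contacts(m, data.frame(chain = "A", resno = 1:6))
  expect_equal(nrow(ct), 0L)
  expect_equal(nrow(protein_rna_contacts(m, data.frame(chain = character(),
                                                       resno = integer()))),
               0L)
})

test_that("a decoy at 3.5 A contacts only the targeted nucleotide", {
  m <- build_aform_model("GCAUGC", decoy_residues = 1, decoy_distance = 3.5,
                         decoy_target = 1)
  ct <- protein_rna_contacts(m, data.frame(chain = "A", resno = 1:6))
  expect_equal(ct$nucleotides, "A:1")
  ct_b <- protein_rna_contacts(m, data.frame(chain = "B", resno = 1:6))
  expect_equal(nrow(ct_b), 0L)
})

test_that("contact counts are invariant to rigid motion", {
  m <- build_aform_model("GCAUGC", decoy_residues = 2, decoy_distance = 3.4)
  nts <- data.frame(chain = "A", resno = 1:6)
  c0 <- protein_rna_contacts(m, nts)
  th <- 1.1
  Ry <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% Ry
  m$atoms$x <- xyz[, 1] - 7; m$atoms$y <- xyz[, 2] + 2; m$atoms$z <- xyz[, 3]
  c1 <- protein_rna_contacts(m, nts)
  expect_equal(c1$n_atom_contacts, c0$n_atom_contacts)
})

test_that("contact averaging over conditions rounds the mean", {
  a <- structure(data.frame(protein_chain = c("P", "Q"),
                            n_atom_contacts = c(27L, 3L),
                            nucleotides = ""), class = c("contact_table",
                                                         "data.frame"))
  b <- structure(data.frame(protein_chain = "P", n_atom_contacts = 28L,
                            nucleotides = ""), class = c("contact_table",
                                                         "data.frame"))
  avg <- average_contacts(a, b)
  expect_equal(avg$n_atom_contacts[avg$protein_chain == "P"], 28L)
  expect_equal(avg$n_atom_contacts[avg$protein_chain == "Q"], 2L)
})

test_that("selecting residues outside RNA chains is an error", {
  m <- build_aform_model("GCAU", decoy_residues = 2)
  expect_error(protein_rna_contacts(m, data.frame(chain = "P", resno = 1)),
               "RNA")
})

test_that("superposition is exact for rigid copies", {
  m <- build_aform_model("GACUGG")
  expect_equal(superpose_rmsd(m, m)$rmsd, 0, tolerance = 1e-9)
  m2 <- m
  m2$atoms$x <- m$atoms$x + 5
  m2$atoms$y <- m$atoms$y + 5
  m2$atoms$z <- m$atoms$z + 5
  expect_equal(superpose_rmsd(m, m2)$rmsd, 0, tolerance = 1e-9)
  th <- 0.6
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% Rz
  m3 <- m
  m3$atoms$x <- xyz[, 1] + 1; m3$atoms$y <- xyz[, 2] - 8; m3$atoms$z <- xyz[, 3]
  fit <- superpose_rmsd(m, m3)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_true(all(fit$per_residue$rmsd < 1e-9))
})

test_that("one displaced atom among N gives RMSD ~ sqrt(1/N)", {
  m <- build_aform_model("GACUGGAC")
  N <- nrow(m$atoms)
  m2 <- m
  m2$atoms$x[10] <- m2$atoms$x[10] + 1.0
  fit <- superpose_rmsd(m, m2)
  expect_equal(fit$rmsd, sqrt(1 / N), tolerance = 0.02)
})

test_that("superposition is symmetric in its arguments", {
  m <- build_aform_model("GACU")
  m2 <- m
  set.seed(9)
  m2$atoms$x <- m2$atoms$x + rnorm(nrow(m2$atoms), 0, 0.3)
  m2$atoms$y <- m2$atoms$y + rnorm(nrow(m2$atoms), 0, 0.3)
  expect_equal(superpose_rmsd(m, m2)$rmsd, superpose_rmsd(m2, m)$rmsd,
               tolerance = 1e-6)
})

test_that("degenerate selections are rejected", {
  df <- data.frame(chain = "A", resno = 1:3, resname = "A", atom = "N1",
                   element = "N", x = c(0, 5, 10), y = 0, z = 0)
  m <- read_structure(write_pdb_text(df))
  expect_error(superpose_rmsd(m, m), "collinear")
  df2 <- df[1:2, ]
  m2 <- read_structure(write_pdb_text(df2))
  expect_error(superpose_rmsd(m2, m2), "fewer than 3")
})
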