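test_that("a 12-bp duplex yields 12 canonical pairs by construction", {
  m <- build_aform_model("GACGUACGUCAG")
  p <- annotate_base_pairs(m, detect_hbonds(m))
  expect_equal(sum(p$pair_class == "canonical_wcf"), 12L)
})

test_that("hairpin loop bases are unpaired ground truth", {
  h <- build_aform_model("GGCGAC", loop = "GAAC")
  truth <- attr(h, "ground_truth")
  expect_equal(truth$paired, c(rep(TRUE, 6), rep(FALSE, 4), rep(TRUE, 6)))
  p <- annotate_base_pairs(h, detect_hbonds(h))
  expect_equal(paired_flags(h, p)$paired, truth$paired)
})

test_that("bulged positions lose partner, pairing and face bonds", {
  m <- build_aform_model("GAUCGAUC", unpaired = c(2, 5))
  truth <- attr(m, "ground_truth")
  expect_false(truth$paired[2])
  expect_equal(sum(m$residues$chain == "B"), 6L)
  b <- detect_hbonds(m)
  expect_equal(count_wcf_face_hbonds(m, b, "A", 2), 0L)
  p <- annotate_base_pairs(m, b)
  expect_equal(paired_flags(m, p)$paired[
    match(paste(truth$chain, truth$resno),
          paste(m$residues$chain, m$residues$resno))], truth$paired)
})

test_that("invalid generator inputs are rejected", {
  expect_error(build_aform_model("ACGX"), "letters")
  expect_error(build_aform_model("ACGU", unpaired = 9), "outside")
  expect_error(synthetic_spec(missing_rate = 1), "missing_rate")
  expect_error(synthetic_spec(duplex_length = 2), "duplex_length")
})

test_that("fixtures are byte-identical for a fixed seed", {
  spec <- synthetic_spec(duplex_length = 12, n_bulges = 2, seed = 42)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_fixtures(spec, d1)
  p2 <- write_fixtures(spec, d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), info = k)
})

test_that("emitted fixtures reload into a table matching ground truth", {
  spec <- synthetic_spec(duplex_length = 25, n_bulges = 5, seed = 19)
  dir <- tempfile()
  paths <- write_fixtures(spec, dir)
  m <- read_structure(paths[["model"]])
  tracks <- read_react(paths[["react"]])
  truth <- read.table(paths[["truth"]], header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  sasa <- shrake_rupley(m)
  bonds <- detect_hbonds(m)
  pairs <- annotate_base_pairs(m, bonds)
  avg <- average_gene_copies(tracks, names(tracks))
  cs <- chain_sequence(m, "A")
  map <- build_numbering_map(cs$sequence, cs$sequence, cs$keys)
  ft <- build_feature_table(m, sasa, bonds, pairs, map, avg)
  tr <- truth[match(paste("A", ft$resno), paste(truth$chain, truth$resno)), ]
  expect_equal(ft$paired, tr$paired)
  expect_equal(ft$base, tr$base)
  # reactivity of non-missing rows equals the simulated average
  sim_avg <- average_gene_copies(read_react(paths[["react"]]),
                                 names(tracks))
  expect_equal(ft$reactivity, sim_avg[ft$probing_position])
})

test_that("simulated tracks follow the generative model exactly at sd 0", {
  s <- small_study()
  spec0 <- synthetic_spec(duplex_length = 40, n_bulges = 8, seed = 11,
                          noise_sd = 0, missing_rate = 0)
  sim <- simulate_reactivity(s$model, "A", s$sasa, s$bonds, spec0)
  avg <- average_gene_copies(sim$tracks, names(sim$tracks))
  expect_equal(avg, sim$mu)
  # G/U positions are missing
  cs <- chain_sequence(s$model, "A")
  gu <- strsplit(cs$sequence, "")[[1]] %in% c("G", "U")
  expect_true(all(is.na(avg[gu])))
})

test_that("reactivity-SASA correlation matches the analytic value", {
  spec <- synthetic_spec(duplex_length = 540, n_bulges = 80, seed = 23)
  m <- synthetic_model(spec)
  sasa <- shrake_rupley(m)
  bonds <- detect_hbonds(m)
  sim <- simulate_reactivity(m, "A", sasa, bonds, spec)
  avg <- average_gene_copies(sim$tracks, names(sim$tracks))
  rs <- reactive_sasa(m, sasa, chains = "A")
  pos <- rs$resno
  ok <- !is.na(avg[pos])
  r_emp <- pearson_r(avg[pos][ok], rs$sasa[ok])
  expect_gt(r_emp, 0)
  # analytic correlation of the log-normal model, given the feature set;
  # averaging k copies scales the noise variance factor accordingly
  mu <- sim$mu[pos][ok]; s2 <- spec$noise_sd^2; k <- spec$n_gene_copies
  sa <- rs$sasa[ok]
  n <- length(mu)
  pvar <- function(v) mean((v - mean(v))^2)
  pcov <- function(a, b) mean((a - mean(a)) * (b - mean(b)))
  # var of a k-copy average of mu*exp(eps): within-position term plus the
  # between-position spread of the expectation
  var_R <- exp(s2) * (exp(s2) - 1) / k * mean(mu^2) + exp(s2) * pvar(mu)
  r_ana <- exp(s2 / 2) * pcov(mu, sa) / sqrt(var_R * pvar(sa))
  se <- (1 - r_emp^2) / sqrt(sum(ok))
  expect_lt(abs(r_emp - r_ana), 3 * se + 0.02)
})

test_that("null generative model calibrates every rule AUC near 0.5", {
  spec0 <- synthetic_spec(duplex_length = 540, n_bulges = 80, seed = 29,
                          sasa_coeff = 0, face_hb_coeff = 0)
  m <- synthetic_model(spec0)
  sasa <- shrake_rupley(m)
  bonds <- detect_hbonds(m)
  pairs <- annotate_base_pairs(m, bonds)
  sim <- simulate_reactivity(m, "A", sasa, bonds, spec0)
  avg <- average_gene_copies(sim$tracks, names(sim$tracks))
  cs <- chain_sequence(m, "A")
  map <- build_numbering_map(cs$sequence, cs$sequence, cs$keys)
  ft <- build_feature_table(m, sasa, bonds, pairs, map, avg)
  g <- run_roc_suite(ft)
  g <- g[!is.na(g$auc), ]
  se <- sqrt((g$n_pos + g$n_neg + 1) / (12 * g$n_pos * g$n_neg))
  expect_true(all(abs(g$auc - 0.5) < 3 * se))
})

test_that("strengthening the H-bond effect never lowers the hb-rule AUC", {
  aucs <- vapply(c(0.0, 0.15, 0.3), function(cf) {
    spec <- synthetic_spec(duplex_length = 60, n_bulges = 12, seed = 37,
                           face_hb_coeff = cf, sasa_coeff = 0,
                           baseline = 0.8)
    m <- synthetic_model(spec)
    sasa <- shrake_rupley(m)
    bonds <- detect_hbonds(m)
    pairs <- annotate_base_pairs(m, bonds)
    sim <- simulate_reactivity(m, "A", sasa, bonds, spec)
    avg <- average_gene_copies(sim$tracks, names(sim$tracks))
    cs <- chain_sequence(m, "A")
    map <- build_numbering_map(cs$sequence, cs$sequence, cs$keys)
    ft <- build_feature_table(m, sasa, bonds, pairs, map, avg)
    lab <- apply_label_rule(ft[ft$base == "A", ], label_rule("hb", k = 1))
    roc_curve(lab$positive, lab$reactivity)$auc
  }, 0)
  expect_true(all(diff(aucs) >= 0))
})

test_that("an overlapping-parameter study tracks its expected AUC", {
  # coefficients chosen so protected bases stay above the max(0, .) floor
  # and the score distributions overlap
  spec <- synthetic_spec(duplex_length = 300, n_bulges = 50, seed = 41,
                         baseline = 0.3, sasa_coeff = 0.05,
                         face_hb_coeff = 0.05)
  m <- synthetic_model(spec)
  sasa <- shrake_rupley(m)
  bonds <- detect_hbonds(m)
  pairs <- annotate_base_pairs(m, bonds)
  sim <- simulate_reactivity(m, "A", sasa, bonds, spec)
  avg <- average_gene_copies(sim$tracks, names(sim$tracks))
  cs <- chain_sequence(m, "A")
  map <- build_numbering_map(cs$sequence, cs$sequence, cs$keys)
  ft <- build_feature_table(m, sasa, bonds, pairs, map, avg)
  for (base in c("A", "C")) {
    sub <- ft[ft$base == base & !is.na(ft$reactivity), ]
    mu <- sim$mu[sub$probing_position]
    lab <- apply_label_rule(sub, label_rule("combo", k = 1))
    emp <- roc_curve(lab$positive, lab$reactivity)$auc
    # per-pair noise sd after averaging 3 copies is reduced; the averaged
    # value is a mean of log-normals, approximated here by matching the
    # first two moments
    s2 <- spec$noise_sd^2 / spec$n_gene_copies
    exp_auc <- expected_auc_oracle(mu[lab$positive], mu[!lab$positive],
                                   sqrt(s2))
    expect_gt(emp, 0.5)
    expect_lt(abs(emp - exp_auc), 0.08)
  }
})
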