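# feature table ---------------------------------------------------------------

#' Join structural features with reactivity per nucleotide
#'
#' Builds the per-nucleotide table every concordance stage consumes:
#' one row per mapped A/C nucleotide carrying its probing reactivity,
#' reactive-atom (N1/N3) SASA, hydrogen-bond counts (any atom, and
#' at/near the WCF face) and paired/unpaired status.  The join is by
#' the numbering map only; rows with missing reactivity are retained
#' and flagged, rows for residues lacking their reactive atom or an
#' entry in the map are absent.
#'
#' @param model a `structure_model`.
#' @param sasa result of [shrake_rupley()].
#' @param bonds result of [detect_hbonds()].
#' @param pairs result of [annotate_base_pairs()].
#' @param map a `numbering_map` for the transcript/chain.
#' @param track averaged numeric reactivity track (probing coordinates).
#' @return data frame of class `feature_table`: `res_uid`, `chain`,
#'   `resno`, `icode`, `probing_position`, `base`, `reactivity`,
#'   `sasa`, `n_hb_any`, `n_hb_face`, `paired`.
#' @export
build_feature_table <- function(model, sasa, bonds, pairs, map, track) {
  stopifnot(inherits(model, "structure_model"), inherits(map, "numbering_map"))
  rsasa <- reactive_sasa(model, sasa)
  pos <- map$map$position[match(rsasa$res_uid, map$map$res_uid)]
  out <- rsasa[!is.na(pos), , drop = FALSE]
  pos <- pos[!is.na(pos)]
  if (nrow(out) == 0)
    stop("empty join: the numbering map covers no A/C nucleotide of the model",
         call. = FALSE)
  if (max(pos) > length(track))
    stop("track shorter than mapped probing positions", call. = FALSE)
  cnt <- .hb_count_table(model, bonds)
  flags <- paired_flags(model, pairs)
  out$probing_position <- pos
  out$reactivity <- track[pos]
  out$n_hb_any <- cnt$n_hb_any[match(out$res_uid, cnt$res_uid)]
  out$n_hb_face <- cnt$n_hb_face[match(out$res_uid, cnt$res_uid)]
  out$paired <- flags$paired[match(out$res_uid, flags$res_uid)]
  out <- out[, c("res_uid", "chain", "resno", "icode", "probing_position",
                 "base", "reactivity", "sasa", "n_hb_any", "n_hb_face",
                 "paired")]
  rownames(out) <- NULL
  structure(out, class = c("feature_table", "data.frame"))
}

#' Add between-condition deltas to a feature table
#'
#' Given feature tables of the same transcript from two conditions,
#' attaches `delta_reactivity`, `delta_sasa` and `delta_hb`
#' (condition a minus condition b, matched by probing position).
#'
#' @param ft_a,ft_b `feature_table` objects for the two conditions.
#' @return `ft_a` with the three delta columns appended.
#' @export
add_differential <- function(ft_a, ft_b) {
  k <- match(ft_a$probing_position, ft_b$probing_position)
  ft_a$delta_reactivity <- ft_a$reactivity - ft_b$reactivity[k]
  ft_a$delta_sasa <- ft_a$sasa - ft_b$sasa[k]
  ft_a$delta_hb <- ft_a$n_hb_any - ft_b$n_hb_any[k]
  ft_a
}

#' Pearson correlation with explicit degeneracy errors
#'
#' Sample Pearson correlation over pairwise-complete values; degenerate
#' input (fewer than 3 complete pairs, or a constant variable) is an
#' error rather than a silent `NA` or 0.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("fewer than 3 complete pairs", call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("correlation undefined: constant input", call. = FALSE)
  stats::cor(x[ok], y[ok])
}

# label rules ------------------------------------------------------------------

#' Structural binary (label rule) for ROC analysis
#'
#' Defines which nucleotides count as structurally *accessible*
#' (positive class, expected reactive) versus *protected* (negative
#' class, expected unreactive):
#' \describe{
#'   \item{unpaired}{positive iff not a member of a canonical WCF pair}
#'   \item{sasa}{negative iff reactive-atom SASA < `sasa_cutoff`}
#'   \item{hb}{negative iff >= `k` hydrogen bonds at/near the WCF face}
#'   \item{combo}{negative iff (SASA < cutoff) OR/AND (face H-bonds >= k)}
#' }
#'
#' @param kind one of `"unpaired"`, `"sasa"`, `"hb"`, `"combo"`.
#' @param k face H-bond threshold (1, 2 or 3) for `hb`/`combo` rules.
#' @param sasa_cutoff SASA threshold in Angstrom^2 (default 1.4; the
#'   boundary is strict, equality counts as accessible).
#' @param boolean_op `"OR"` or `"AND"` for `combo` rules.
#' @return list of class `label_rule` with a descriptive `label`.
#' @export
label_rule <- function(kind = c("unpaired", "sasa", "hb", "combo"),
                       k = 1L, sasa_cutoff = 1.4,
                       boolean_op = c("OR", "AND")) {
  kind <- match.arg(kind)
  boolean_op <- match.arg(boolean_op)
  if (kind %in% c("hb", "combo")) stopifnot(k %in% 1:3)
  stopifnot(sasa_cutoff > 0)
  label <- switch(kind,
                  unpaired = "unpaired",
                  sasa = sprintf("sasa<%.1f", sasa_cutoff),
                  hb = sprintf("hb>=%d", k),
                  combo = sprintf("sasa<%.1f %s hb>=%d", sasa_cutoff,
                                  boolean_op, k))
  structure(list(kind = kind, k = as.integer(k), sasa_cutoff = sasa_cutoff,
                 boolean_op = boolean_op, label = label),
            class = "label_rule")
}

#' Apply a label rule to a feature table
#'
#' @param rows a `feature_table`.
#' @param rule a [label_rule()].
#' @return `rows` with a logical `positive` column (TRUE = accessible).
#' @export
apply_label_rule <- function(rows, rule) {
  stopifnot(inherits(rule, "label_rule"))
  need <- switch(rule$kind, unpaired = "paired", sasa = "sasa",
                 hb = "n_hb_face", combo = c("sasa", "n_hb_face"))
  if (!all(need %in% names(rows)))
    stop("feature table lacks column(s) ", paste(need, collapse = ", "),
         " required by rule '", rule$label, "'", call. = FALSE)
  negative <- switch(rule$kind,
    unpaired = rows$paired,
    sasa = rows$sasa < rule$sasa_cutoff,
    hb = rows$n_hb_face >= rule$k,
    combo = if (rule$boolean_op == "OR")
      (rows$sasa < rule$sasa_cutoff) | (rows$n_hb_face >= rule$k)
    else
      (rows$sasa < rule$sasa_cutoff) & (rows$n_hb_face >= rule$k))
  rows$positive <- !negative
  rows
}

# ROC / AUC --------------------------------------------------------------------

#' ROC curve of reactivity against a structural binary
#'
#' Sweeps a decision threshold over the distinct reactivity scores
#' (ties grouped at one threshold; a position is called reactive when
#' its score >= threshold) and reports TPR/FPR series and the
#' trapezoidal area under the curve.  The tie-corrected Mann-Whitney
#' probability `P(score_pos > score_neg) + P(tie)/2` is returned
#' alongside as a cross-check; the two agree identically for grouped
#' ties.  Rows with missing scores are excluded.
#'
#' @param labels logical vector, TRUE = positive (accessible) class.
#' @param scores numeric scores (reactivity).
#' @param filter_below optional low-reactivity filter: rows with
#'   `score < filter_below` are discarded before the sweep (used for
#'   base-pairing ROCs, where unreactive-but-unpaired positions
#'   otherwise dominate the false negatives).
#' @return list of class `roc_curve`: `thresholds` (descending),
#'   `tpr`, `fpr` (each starting at 0,0 and ending at 1,1), `auc`,
#'   `auc_mw`, `n_pos`, `n_neg`, `filter_below`.
#' @export
roc_curve <- function(labels, scores, filter_below = NULL) {
  if (length(labels) != length(scores))
    stop("labels and scores lengths differ", call. = FALSE)
  ok <- !is.na(scores) & !is.na(labels)
  labels <- labels[ok]; scores <- scores[ok]
  if (!is.null(filter_below)) {
    keep <- scores >= filter_below
    labels <- labels[keep]; scores <- scores[keep]
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("degenerate labelling: need at least one positive and one negative",
         call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  # counts of pos/neg at each distinct score, cumulated over the sweep
  pos_at <- vapply(thr, function(t) sum(scores == t & labels), 0)
  neg_at <- vapply(thr, function(t) sum(scores == t & !labels), 0)
  tpr <- c(0, cumsum(pos_at) / n_pos)
  fpr <- c(0, cumsum(neg_at) / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  # tie-corrected Mann-Whitney probability via midranks
  r <- rank(scores)
  auc_mw <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 auc_mw = auc_mw, n_pos = n_pos, n_neg = n_neg,
                 filter_below = filter_below),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC %.4f (%d positives, %d negatives%s)\n",
              x$auc, x$n_pos, x$n_neg,
              if (is.null(x$filter_below)) ""
              else sprintf(", scores < %g filtered", x$filter_below)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, add = FALSE, col = "firebrick", ...) {
  if (!add) {
    plot(x$fpr, x$tpr, type = "l", col = col, lwd = 2,
         xlab = "False positive rate", ylab = "True positive rate",
         xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey50")
  } else {
    graphics::lines(x$fpr, x$tpr, col = col, lwd = 2, ...)
  }
  invisible(x)
}

#' Default rule grid for the ROC suite
#'
#' The grid examined per base: unpaired, SASA, face H-bonds at k = 1..3,
#' and SASA-OR/AND-H-bond combinations at k = 1..3.
#'
#' @param sasa_cutoff SASA threshold passed to each rule.
#' @return list of [label_rule()] objects.
#' @export
default_rules <- function(sasa_cutoff = 1.4) {
  c(list(label_rule("unpaired"), label_rule("sasa", sasa_cutoff = sasa_cutoff)),
    lapply(1:3, function(k) label_rule("hb", k = k)),
    lapply(1:3, function(k) label_rule("combo", k = k,
                                       sasa_cutoff = sasa_cutoff,
                                       boolean_op = "OR")),
    lapply(1:3, function(k) label_rule("combo", k = k,
                                       sasa_cutoff = sasa_cutoff,
                                       boolean_op = "AND")))
}

#' ROC/AUC grid over label rules and bases
#'
#' Runs [roc_curve()] for every rule and base combination.  The
#' low-reactivity filter is applied only to the base-pairing
#' (`unpaired`) rule unless `filter_all` is set: for the other rules
#' the unfiltered reactivities are used.
#'
#' @param rows a `feature_table`.
#' @param rules list of [label_rule()] objects (default [default_rules()]).
#' @param bases bases analysed separately (default A and C).
#' @param filter_below low-reactivity cutoff for base-pairing ROCs
#'   (`NULL` to disable).
#' @param filter_all apply the filter to every rule, not just pairing.
#' @return data frame `rule`, `base`, `auc`, `n_pos`, `n_neg`,
#'   `filtered`; the `roc_curve` objects are attached as attribute
#'   `curves` (named `rule|base`).  A cell whose labelling is
#'   one-class (no nucleotide on one side of the binary) has no
#'   defined AUC and is reported as `NA`.
#' @export
run_roc_suite <- function(rows, rules = default_rules(), bases = c("A", "C"),
                          filter_below = NULL, filter_all = FALSE) {
  out <- list(); curves <- list()
  for (base in bases) {
    sub <- rows[rows$base == base, , drop = FALSE]
    if (nrow(sub) == 0) stop("no rows for base ", base, call. = FALSE)
    for (rule in rules) {
      lab <- apply_label_rule(sub, rule)
      fb <- if (rule$kind == "unpaired" || filter_all) filter_below else NULL
      key <- paste(rule$label, base, sep = "|")
      rc <- tryCatch(roc_curve(lab$positive, lab$reactivity, filter_below = fb),
                     error = function(e) e)
      if (inherits(rc, "error")) {
        # a one-class cell (e.g. no nucleotide reaches the H-bond threshold)
        # has no defined AUC; record it rather than abort the grid
        out[[key]] <- data.frame(rule = rule$label, base = base,
                                 auc = NA_real_,
                                 n_pos = sum(lab$positive),
                                 n_neg = sum(!lab$positive),
                                 filtered = !is.null(fb),
                                 stringsAsFactors = FALSE)
        next
      }
      curves[[key]] <- rc
      out[[key]] <- data.frame(rule = rule$label, base = base, auc = rc$auc,
                               n_pos = rc$n_pos, n_neg = rc$n_neg,
                               filtered = !is.null(fb),
                               stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "curves") <- curves
  res
}

# bundled concordance analysis -------------------------------------------------

#' Structure-probing concordance analysis
#'
#' Convenience wrapper producing the full concordance summary for one
#' condition: Pearson correlations of reactivity against SASA and
#' against the any-atom hydrogen-bond count, plus the ROC/AUC grid.
#'
#' @param rows a `feature_table`.
#' @param rules list of label rules (default [default_rules()]).
#' @param filter_below low-reactivity filter for pairing ROCs
#'   (default 0.2; `NULL` disables).
#' @return object of class `probe_concordance`: list with `features`,
#'   `r_sasa`, `r_hb`, `roc` (the grid with attached curves), `n`.
#' @export
probe_concordance <- function(rows, rules = default_rules(),
                              filter_below = 0.2) {
  ok <- !is.na(rows$reactivity)
  r_sasa <- pearson_r(rows$sasa[ok], rows$reactivity[ok])
  r_hb <- pearson_r(rows$n_hb_any[ok], rows$reactivity[ok])
  roc <- run_roc_suite(rows, rules = rules, filter_below = filter_below)
  structure(list(features = rows, r_sasa = r_sasa, r_hb = r_hb, roc = roc,
                 n = sum(ok)),
            class = "probe_concordance")
}

#' @export
print.probe_concordance <- function(x, ...) {
  cat("probe_concordance over", x$n, "nucleotides with reactivity\n")
  cat(sprintf("  r(reactivity, SASA)      = %+.3f\n", x$r_sasa))
  cat(sprintf("  r(reactivity, H-bonds)   = %+.3f\n", x$r_hb))
  cat("  AUC grid:\n")
  g <- x$roc
  for (i in seq_len(nrow(g)))
    cat(sprintf("    %-22s %s  AUC %.3f  (%d+/%d-)%s\n", g$rule[i], g$base[i],
                g$auc[i], g$n_pos[i], g$n_neg[i],
                if (g$filtered[i]) "  [filtered]" else ""))
  invisible(x)
}

#' @export
summary.probe_concordance <- function(object, ...) {
  print(object)
  invisible(object$roc)
}

#' @export
plot.probe_concordance <- function(x, base = "A", ...) {
  curves <- attr(x$roc, "curves")
  keys <- grep(paste0("\\|", base, "$"), names(curves), value = TRUE)
  cols <- grDevices::hcl.colors(max(length(keys), 2), "Dark 3")
  first <- TRUE
  for (i in seq_along(keys)) {
    plot(curves[[keys[i]]], add = !first, col = cols[i],
         main = if (first) paste("ROC curves, base", base) else NULL)
    first <- FALSE
  }
  graphics::legend("bottomright", legend = sub("\\|.*", "", keys),
                   col = cols[seq_along(keys)], lwd = 2, cex = 0.7, bty = "n")
  invisible(x)
}
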