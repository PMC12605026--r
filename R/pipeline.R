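# Declarative run configuration and end-to-end pipeline -----------------------

.PARAM_DEFAULTS <- list(probe_radius = 1.4, n_points = 400,
                        hbond_min = 2.0, hbond_max = 3.5,
                        contact_cutoff = 4.0, sasa_cutoff = 1.4,
                        reactivity_filter = 0.2, diff_threshold = 0.5)

# tiny polynomial hash so output headers can state which config produced them
.config_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Validate a pipeline run configuration
#'
#' Reads a JSON run configuration, checks every invariant, injects
#' defaults for omitted parameters and reports all problems at once.
#' A configuration names one or two *conditions* (e.g. growth
#' substrates), each with a structure file, the RNA chain to analyse,
#' a `.react` file and the gene-copy transcript ids to average.
#'
#' @param path path to a JSON configuration file.
#' @return a validated list of class `run_config` (with defaults
#'   filled in), or an error carrying the aggregated problem list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  problems <- character(0)
  known_top <- c("conditions", "params", "out_dir", "seed")
  extra <- setdiff(names(cfg), known_top)
  if (length(extra))
    warning("ignoring unknown config key(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  if (is.null(cfg$conditions) || length(cfg$conditions) < 1)
    problems <- c(problems, "no conditions defined")
  for (i in seq_along(cfg$conditions)) {
    cd <- cfg$conditions[[i]]
    where <- paste0("condition ", i, if (!is.null(cd$name)) paste0(" (", cd$name, ")"))
    for (f in c("structure", "react")) {
      if (is.null(cd[[f]])) problems <- c(problems, paste0(where, ": missing '", f, "'"))
      else if (!file.exists(cd[[f]]))
        problems <- c(problems, paste0(where, ": file not found: ", cd[[f]]))
    }
    if (is.null(cd$chain)) problems <- c(problems, paste0(where, ": missing 'chain'"))
    if (is.null(cd$gene_ids) || length(cd$gene_ids) < 1)
      problems <- c(problems, paste0(where, ": missing 'gene_ids'"))
  }
  params <- utils::modifyList(.PARAM_DEFAULTS,
                              if (is.null(cfg$params)) list() else
                                cfg$params[names(cfg$params) %in% names(.PARAM_DEFAULTS)])
  unknown_par <- setdiff(names(cfg$params), names(.PARAM_DEFAULTS))
  if (length(unknown_par))
    warning("ignoring unknown parameter(s): ",
            paste(unknown_par, collapse = ", "), call. = FALSE)
  if (params$probe_radius <= 0) problems <- c(problems, "probe_radius must be > 0")
  if (params$n_points < 16) problems <- c(problems, "n_points must be >= 16")
  if (params$hbond_min <= 0 || params$hbond_max < params$hbond_min)
    problems <- c(problems, "invalid hbond window")
  if (params$contact_cutoff <= 0) problems <- c(problems, "contact_cutoff must be > 0")
  if (params$sasa_cutoff <= 0) problems <- c(problems, "sasa_cutoff must be > 0")
  if (params$diff_threshold < 0) problems <- c(problems, "diff_threshold must be >= 0")
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  cfg$params <- params
  if (is.null(cfg$out_dir)) cfg$out_dir <- "probeconcord_out"
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$hash <- .config_hash(cfg[c("conditions", "params", "seed")])
  class(cfg) <- "run_config"
  cfg
}

# '#'-prefixed provenance header for tabular outputs
.tsv_header <- function(cfg, stage) {
  c(sprintf("# probeconcord %s", as.character(utils::packageVersion("probeconcord"))),
    sprintf("# stage: %s", stage),
    sprintf("# config: %s", cfg$hash),
    sprintf("# params: %s",
            paste(names(cfg$params), unlist(cfg$params), sep = "=",
                  collapse = " ")))
}

.write_stage_tsv <- function(df, path, cfg, stage) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(.tsv_header(cfg, stage), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full concordance pipeline
#'
#' Executes, per condition: structure loading, per-atom SASA,
#' hydrogen-bond detection, base-pair annotation, gene-copy averaging,
#' numbering-map construction, the feature join and the
#' correlation/ROC summary; with two conditions it additionally
#' computes differential reactivity, the selection rule and
#' protein-RNA contacts for the selected nucleotides, averaged across
#' conditions.  All tabular outputs carry a `#` header with package
#' version, configuration hash and parameters.
#'
#' @param config a `run_config` from [validate_config()], or a path to
#'   a JSON configuration.
#' @param quiet suppress progress messages (parameter echo in file
#'   headers is never suppressed).
#' @return named list of output file paths, invisibly; the in-memory
#'   results are attached as attribute `results`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[probeconcord] ", ...)
  outs <- character(0); results <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed [E_%s]: %s", name, toupper(name),
                   conditionMessage(e)), call. = FALSE))
  }

  cond_data <- list()
  for (cd in config$conditions) {
    nm <- if (is.null(cd$name)) cd$chain else cd$name
    say("condition '", nm, "': loading ", cd$structure)
    model <- stage("load", read_structure(cd$structure))
    sasa <- stage("sasa", shrake_rupley(model, sasa_params(
      probe_radius = p$probe_radius, n_points = p$n_points)))
    bonds <- stage("hbonds", detect_hbonds(model, p$hbond_min, p$hbond_max))
    pairs <- stage("pairs", annotate_base_pairs(model, bonds))
    say("condition '", nm, "': ", nrow(bonds), " H-bonds, ",
        sum(pairs$pair_class == "canonical_wcf"), " canonical pairs")
    tracks <- stage("react", read_react(cd$react))
    avg <- stage("average", average_gene_copies(tracks,
                                                as.character(cd$gene_ids)))
    cs <- stage("sequence", chain_sequence(model, cd$chain))
    track_seq <- if (is.null(cd$track_sequence)) cs$sequence else cd$track_sequence
    map <- stage("map", build_numbering_map(track_seq, cs$sequence, cs$keys))
    ft <- stage("features",
                build_feature_table(model, sasa, bonds, pairs, map, avg))
    fb <- if (p$reactivity_filter > 0) p$reactivity_filter else NULL
    conc <- stage("concordance",
                  probe_concordance(ft, rules = default_rules(p$sasa_cutoff),
                                    filter_below = fb))
    say("condition '", nm, "': ", nrow(ft), " feature rows, r(sasa) = ",
        sprintf("%+.3f", conc$r_sasa))
    f1 <- .write_stage_tsv(ft, file.path(config$out_dir,
                                         paste0("features_", nm, ".tsv")),
                           config, paste0("features:", nm))
    f2 <- .write_stage_tsv(conc$roc, file.path(config$out_dir,
                                               paste0("roc_grid_", nm, ".tsv")),
                           config, paste0("roc:", nm))
    curves <- attr(conc$roc, "curves")
    f3 <- file.path(config$out_dir, paste0("roc_", nm, ".json"))
    jsonlite::write_json(lapply(curves, function(rc)
      rc[c("thresholds", "tpr", "fpr", "auc", "n_pos", "n_neg")]),
      f3, digits = NA, auto_unbox = TRUE)
    outs <- c(outs, features = f1, roc_grid = f2, roc_json = f3)
    cond_data[[nm]] <- list(model = model, avg = avg, map = map, ft = ft,
                            conc = conc, name = nm)
  }

  cors <- do.call(rbind, lapply(cond_data, function(cc)
    data.frame(condition = cc$name, n = cc$conc$n, r_sasa = cc$conc$r_sasa,
               r_hb = cc$conc$r_hb, stringsAsFactors = FALSE)))
  fc <- .write_stage_tsv(cors, file.path(config$out_dir, "correlations.tsv"),
                         config, "correlations")
  outs <- c(outs, correlations = fc)

  if (length(cond_data) >= 2) {
    a <- cond_data[[1]]; b <- cond_data[[2]]
    diff <- stage("differential",
                  differential(a$avg, b$avg, threshold = p$diff_threshold))
    sel <- stage("exclude", exclude_unmodeled(diff, a$map, quiet = quiet))
    say(sum(diff$selected), " positions selected (|delta| >= ",
        p$diff_threshold, "), ", sum(sel$selected), " modelled")
    fd <- .write_stage_tsv(diff, file.path(config$out_dir, "differential.tsv"),
                           config, "differential")
    outs <- c(outs, differential = fd)
    sel_nt <- sel[sel$selected, c("chain", "resno", "icode")]
    cts <- lapply(cond_data[1:2], function(cc)
      stage("contacts", protein_rna_contacts(cc$model, sel_nt,
                                             cutoff = p$contact_cutoff)))
    avg_ct <- average_contacts(cts[[1]], cts[[2]])
    fk <- .write_stage_tsv(avg_ct, file.path(config$out_dir, "contacts.tsv"),
                           config, "contacts")
    outs <- c(outs, contacts = fk)
    results$differential <- diff
    results$selected <- sel
    results$contacts <- avg_ct
  }
  results$conditions <- cond_data
  say("done; outputs in ", config$out_dir)
  out <- outs
  attr(out, "results") <- results
  invisible(out)
}
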