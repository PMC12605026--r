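# .react reactivity tracks ----------------------------------------------------

#' Read StructureFold-style `.react` reactivity tracks
#'
#' The `.react` format alternates a transcript-id line with a
#' tab-separated value line, one value per nucleotide position (1-based)
#' with `NA` marking positions without data.  Gzip-compressed files are
#' read transparently.
#'
#' @param path file path (`.react` or `.react.gz` style text).
#' @return named list of numeric vectors (one per transcript, `NA` for
#'   missing positions), class `react_set`.
#' @export
read_react <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(structure(stats::setNames(list(), character(0)),
                     class = "react_set"))
  if (length(lines) %% 2L != 0L)
    stop("malformed .react file (odd number of non-empty lines): ", path,
         call. = FALSE)
  ids <- trimws(lines[seq(1, length(lines), by = 2)])
  vals <- lapply(seq_along(ids), function(k) {
    ln <- 2L * k
    tok <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(tok))
    bad <- is.na(v) & !(toupper(trimws(tok)) %in% c("NA", ""))
    if (any(bad))
      stop("non-numeric token '", tok[which(bad)[1]], "' at line ", ln,
           " of ", path, call. = FALSE)
    v
  })
  structure(stats::setNames(vals, ids), class = "react_set")
}

#' Write reactivity tracks in `.react` format
#'
#' @param tracks named list of numeric vectors (or a `react_set`).
#' @param path output path; a `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_react <- function(tracks, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (id in names(tracks)) {
    writeLines(id, con)
    v <- tracks[[id]]
    writeLines(paste(ifelse(is.na(v), "NA", format(v, digits = 15,
                                                   scientific = FALSE,
                                                   trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Average reactivity across rRNA gene copies
#'
#' rRNA operons occur in near-identical genomic copies whose probing
#' tracks describe the same molecule; per position, the arithmetic mean
#' over the copies with a present value is taken, and a position is
#' missing only when it is missing in every copy.
#'
#' @param tracks a `react_set` (or named list of numeric vectors).
#' @param ids transcript ids of the copies to average.
#' @return numeric vector (the averaged track).
#' @export
average_gene_copies <- function(tracks, ids) {
  miss <- setdiff(ids, names(tracks))
  if (length(miss))
    stop("transcript id(s) not in track set: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- tracks[as.character(ids)]
  len <- unique(lengths(m))
  if (length(len) != 1L)
    stop("gene-copy tracks have unequal lengths: ",
         paste(lengths(m), collapse = ", "), call. = FALSE)
  mat <- do.call(rbind, m)
  out <- colMeans(mat, na.rm = TRUE)
  out[colSums(!is.na(mat)) == 0L] <- NA_real_
  out
}

#' Differential reactivity between growth conditions
#'
#' Computes `delta = reactivity_a - reactivity_b` per position (the
#' first argument is the reference condition, e.g. methanol) and marks
#' positions with `|delta| >= threshold` as highly differentially
#' reactive.  Positions with either value missing are excluded and
#' counted in attribute `n_excluded`.
#'
#' @param track_a,track_b averaged numeric tracks of equal length.
#' @param sequence optional transcript sequence; when supplied, only
#'   A/C positions are considered and a `base` column is filled in.
#' @param threshold selection threshold on `|delta|` (default 0.5,
#'   inclusive).
#' @return data frame `position`, `base`, `reactivity_a`,
#'   `reactivity_b`, `delta`, `abs_delta`, `selected`.
#' @export
differential <- function(track_a, track_b, sequence = NULL, threshold = 0.5) {
  if (length(track_a) != length(track_b))
    stop("tracks have different lengths (", length(track_a), " vs ",
         length(track_b), ")", call. = FALSE)
  pos <- seq_along(track_a)
  base <- rep(NA_character_, length(pos))
  keep <- rep(TRUE, length(pos))
  if (!is.null(sequence)) {
    letters <- strsplit(chartr("t", "u", chartr("T", "U", sequence)), "")[[1]]
    if (length(letters) != length(pos))
      stop("sequence length does not match track length", call. = FALSE)
    base <- toupper(letters)
    keep <- base %in% c("A", "C")
  }
  present <- !is.na(track_a) & !is.na(track_b)
  n_excluded <- sum(keep & !present)
  keep <- keep & present
  delta <- track_a[keep] - track_b[keep]
  out <- data.frame(position = pos[keep], base = base[keep],
                    reactivity_a = track_a[keep], reactivity_b = track_b[keep],
                    delta = delta, abs_delta = abs(delta),
                    selected = abs(delta) >= threshold,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "threshold") <- threshold
  out
}

# numbering map ----------------------------------------------------------------

#' Map probing-track positions to model residue numbering
#'
#' Probing coordinates and model author numbering for the same rRNA can
#' differ by small offsets (unmodelled positions, historical numbering).
#' The two nucleotide sequences are aligned globally (match +1,
#' mismatch -1, gap -2; T and U equivalent) and matched columns with
#' identical bases define the mapping.
#'
#' @param track_sequence transcript sequence in probing coordinates.
#' @param model_sequence chain sequence from [chain_sequence()].
#' @param model_keys data frame of residue keys in chain order (the
#'   `keys` element of [chain_sequence()]).
#' @param min_identity refuse the mapping below this alignment identity
#'   (default 0.8), which usually indicates the wrong chain.
#' @return list of class `numbering_map`: `map` (data frame
#'   `position`, `chain`, `resno`, `icode`, `res_uid`), `offset`
#'   (dominant `resno - position`), `identity`, `unmapped_positions`,
#'   `unmapped_residues`.
#' @export
build_numbering_map <- function(track_sequence, model_sequence, model_keys,
                                min_identity = 0.8) {
  s1 <- toupper(chartr("Uu", "Tt", track_sequence))
  s2 <- toupper(chartr("Uu", "Tt", model_sequence))
  if (!nzchar(s1) || !nzchar(s2)) stop("empty sequence", call. = FALSE)
  if (nchar(s2) != nrow(model_keys))
    stop("model_keys rows must match model_sequence length", call. = FALSE)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
                                      substitutionMatrix = submat,
                                      gapOpening = 0, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ip <- cumsum(p != "-")
  is_ <- cumsum(s != "-")
  match_col <- p != "-" & s != "-" & p == s
  aligned_col <- p != "-" & s != "-"
  identity <- if (any(aligned_col)) mean(p[aligned_col] == s[aligned_col]) else 0
  if (identity < min_identity)
    stop(sprintf(paste0("alignment identity %.2f below %.2f - the track and ",
                        "chain sequences disagree (wrong chain?)"),
                 identity, min_identity), call. = FALSE)
  pos <- ip[match_col]
  ridx <- is_[match_col]
  map <- data.frame(position = pos,
                    chain = model_keys$chain[ridx],
                    resno = model_keys$resno[ridx],
                    icode = model_keys$icode[ridx],
                    res_uid = model_keys$res_uid[ridx],
                    stringsAsFactors = FALSE)
  offs <- map$resno - map$position
  offset <- as.integer(names(sort(table(offs), decreasing = TRUE))[1])
  structure(list(map = map, offset = offset, identity = identity,
                 unmapped_positions = setdiff(seq_len(nchar(s1)), pos),
                 unmapped_residues = model_keys$res_uid[-ridx]),
            class = "numbering_map")
}

#' @export
print.numbering_map <- function(x, ...) {
  cat(sprintf(paste0("numbering_map: %d positions mapped (identity %.3f), ",
                     "dominant offset %+d\n  %d track positions and %d model ",
                     "residues unmapped\n"),
              nrow(x$map), x$identity, x$offset,
              length(x$unmapped_positions), length(x$unmapped_residues)))
  invisible(x)
}

#' Drop differential records without a modelled residue
#'
#' Selected differentially reactive positions can only be interpreted
#' structurally when the corresponding residue is present (fully
#' modelled) in the coordinate model; records at unmapped positions are
#' dropped with a message each.
#'
#' @param records result of [differential()].
#' @param map a `numbering_map` for the same transcript.
#' @param quiet suppress per-record messages.
#' @return the surviving records, with mapped `chain`/`resno` columns.
#' @export
exclude_unmodeled <- function(records, map, quiet = FALSE) {
  stopifnot(inherits(map, "numbering_map"))
  idx <- match(records$position, map$map$position)
  drop <- is.na(idx)
  if (!quiet && any(drop & records$selected))
    for (p in records$position[drop & records$selected])
      message("dropping selected position ", p, ": no modelled residue")
  out <- records[!drop, , drop = FALSE]
  k <- idx[!drop]
  out$chain <- map$map$chain[k]
  out$resno <- map$map$resno[k]
  out$icode <- map$map$icode[k]
  out$res_uid <- map$map$res_uid[k]
  rownames(out) <- NULL
  out
}

#' G+C content of a sequence
#'
#' @param sequence nucleotide string (A/C/G/U/T; N and gaps ignored).
#' @return fraction of counted letters that are G or C.
#' @export
gc_content <- function(sequence) {
  letters <- strsplit(toupper(sequence), "")[[1]]
  counted <- letters %in% c("A", "C", "G", "T", "U")
  if (!any(counted)) stop("no countable nucleotides in sequence", call. = FALSE)
  sum(letters %in% c("G", "C")) / sum(counted)
}
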