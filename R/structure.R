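#' @useDynLib probeconcord, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor pnorm qnorm rnorm runif rbinom sd setNames aggregate
#' @importFrom utils read.table write.table head modifyList
"_PACKAGE"

# residue-name vocabularies ---------------------------------------------------

.RNA_CANONICAL <- c(A = "A", C = "C", G = "G", U = "U",
                    DA = "A", DC = "C", DG = "G", DT = "U", DU = "U")

# common modified nucleosides -> parent base
.RNA_MODIFIED <- c(
  OMG = "G", `2MG` = "G", M2G = "G", `7MG` = "G", G7M = "G", `1MG` = "G",
  QUO = "G", YG  = "G",
  OMA = "A", A2M = "A", `1MA` = "A", MA6 = "A", `6MA` = "A", `2MA` = "A",
  OMC = "C", `5MC` = "C", `4AC` = "C", `4OC` = "C", M4C = "C",
  OMU = "U", PSU = "U", `5MU` = "U", UR3 = "U", H2U = "U", `4SU` = "U",
  `3MU` = "U", `70U` = "U", T   = "U")

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V", "M", "U", "O")

.SOLVENT <- c("HOH", "WAT", "DOD", "MG", "K", "NA", "CL", "ZN", "MN", "FE",
              "CA", "NI", "CU", "CO", "BR", "IOD", "SO4", "PO4")

# classify a residue name: list(base = parent base letter or NA,
# modified = flag, kind = "nt" | "aa" | "other")
.classify_resname <- function(name) {
  name <- toupper(trimws(name))
  if (name %in% names(.RNA_CANONICAL))
    return(list(base = unname(.RNA_CANONICAL[name]), modified = FALSE, kind = "nt"))
  if (name %in% names(.RNA_MODIFIED))
    return(list(base = unname(.RNA_MODIFIED[name]), modified = TRUE, kind = "nt"))
  if (name %in% .AA3)
    return(list(base = .AA1[match(name, .AA3)], modified = FALSE, kind = "aa"))
  if (name %in% .SOLVENT)
    return(list(base = NA_character_, modified = FALSE, kind = "other"))
  # heuristic for unlisted modified nucleosides: a short code whose letters
  # reduce to a single canonical base (e.g. "8AZG" -> G)
  letters_only <- gsub("[^ACGU]", "", name)
  u <- unique(strsplit(letters_only, "")[[1]])
  if (nchar(name) <= 3 && length(u) == 1)
    return(list(base = u, modified = TRUE, kind = "nt"))
  list(base = NA_character_, modified = FALSE, kind = "other")
}

# constructor -----------------------------------------------------------------

# Build a structure_model from a flat atom table.  Internal: both the file
# readers and the synthetic generator funnel through here, so altloc
# resolution, hydrogen dropping and chain-kind inference live in one place.
.structure_model <- function(atoms, entry_id = "UNKNOWN",
                             drop_hydrogens = TRUE) {
  stopifnot(all(c("chain", "resno", "icode", "resname", "atom", "element",
                  "x", "y", "z", "occupancy", "altloc") %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("empty model: no atoms", call. = FALSE)
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  if (drop_hydrogens) {
    h <- atoms$element %in% c("H", "D")
    atoms <- atoms[!h, , drop = FALSE]
    if (nrow(atoms) == 0L) stop("empty model: only hydrogens", call. = FALSE)
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates", call. = FALSE)

  # altloc resolution: keep highest occupancy, ties broken by altloc order
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occupancy, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }
  rownames(atoms) <- NULL

  rkey <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  res_first <- !duplicated(rkey)
  residues <- data.frame(chain = atoms$chain[res_first],
                         resno = atoms$resno[res_first],
                         icode = atoms$icode[res_first],
                         resname = atoms$resname[res_first],
                         stringsAsFactors = FALSE)
  cls <- lapply(residues$resname, .classify_resname)
  residues$base <- vapply(cls, function(v) if (is.na(v$base)) NA_character_ else v$base, "")
  residues$modified <- vapply(cls, function(v) v$modified, TRUE)
  residues$kind <- vapply(cls, function(v) v$kind, "")
  residues$res_uid <- seq_len(nrow(residues))
  atoms$res_uid <- residues$res_uid[match(rkey, rkey[res_first])]

  chain_kind <- vapply(split(residues$kind, residues$chain), function(k) {
    if (mean(k == "nt") > 0.5) "rna"
    else if (mean(k == "aa") > 0.5) "protein"
    else "other"
  }, "")

  structure(list(entry_id = entry_id, atoms = atoms, residues = residues,
                 chain_kind = chain_kind),
            class = "structure_model")
}

# readers ---------------------------------------------------------------------

#' Read a coordinate model from PDB or mmCIF
#'
#' Parses a coordinate file into a uniform hierarchical model:
#' chains of residues of atoms, using *author* chain identifiers and
#' residue numbers throughout (the numbering used in deposited-entry
#' figures and tables).  Alternate locations are resolved by keeping the
#' location with the highest occupancy (ties broken by altloc identifier
#' order), hydrogens are dropped, and waters and free ions are retained
#' but classified as chain kind `"other"` so that geometric stages can
#' skip them.  Multi-model files contribute model 1 only.
#'
#' @param source path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (by file extension), `"pdb"` or `"cif"`.
#' @param drop_hydrogens drop H/D atoms on load (default `TRUE`); every
#'   downstream distance criterion is heteroatom-based.
#' @return an object of class `structure_model` with elements
#'   `entry_id`, `atoms` (flat atom table with `res_uid` linking into
#'   `residues`), `residues` (one row per residue, with parent `base`
#'   letter and `modified` flag for nucleotides) and `chain_kind`
#'   (named vector: `"rna"`, `"protein"` or `"other"` per chain).
#' @export
read_structure <- function(source, format = c("auto", "pdb", "cif"),
                           drop_hydrogens = TRUE) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("file not found: ", source, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", source)))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(source, verbose = FALSE,
                                         multi = FALSE, rm.alt = FALSE)
    else suppressWarnings(bio3d::read.cif(source, verbose = FALSE)),
    error = function(e) stop("cannot parse ", source, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("empty model: ", source, " contains no atoms", call. = FALSE)
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  miss <- is.na(elem) | !nzchar(trimws(elem))
  elem[miss] <- .element_from_name(at$elety[miss], at$resid[miss])
  atoms <- data.frame(chain = as.character(at$chain),
                      resno = as.integer(at$resno),
                      icode = ifelse(is.na(at$insert), "", as.character(at$insert)),
                      resname = as.character(at$resid),
                      atom = as.character(at$elety),
                      element = trimws(elem),
                      x = at$x, y = at$y, z = at$z,
                      occupancy = at$o,
                      altloc = ifelse(is.na(at$alt), "", as.character(at$alt)),
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  entry <- toupper(sub("\\.[^.]*$", "", basename(source)))
  .structure_model(atoms, entry_id = entry, drop_hydrogens = drop_hydrogens)
}

# derive element symbol from an atom name (e.g. "C1'" -> C, "OP1" -> O,
# "MG" in residue MG -> MG)
.element_from_name <- function(name, resname) {
  name <- toupper(trimws(name))
  two <- c("MG", "ZN", "MN", "FE", "NA", "CL", "BR", "CA", "NI", "CU", "CO")
  out <- character(length(name))
  for (i in seq_along(name)) {
    if (name[i] %in% two && !is.na(resname[i]) &&
        toupper(trimws(resname[i])) %in% .SOLVENT) {
      out[i] <- name[i]
    } else {
      stripped <- gsub("[^A-Z]", "", name[i])
      out[i] <- substr(stripped, 1, 1)
    }
  }
  out
}

#' Write a structure model to PDB format
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  n <- nrow(at)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resname, chain = at$chain,
                   insert = ifelse(nzchar(at$icode), at$icode, NA),
                   elety = at$atom, o = at$occupancy, b = rep(0, n),
                   elesy = at$element)
  invisible(path)
}

# selectors -------------------------------------------------------------------

#' One-letter sequence of a chain
#'
#' Modified nucleosides map to their parent base letter and are flagged;
#' unknown residues map to `"N"` (RNA) or `"X"` (protein).
#'
#' @param model a `structure_model`.
#' @param chain_id author chain identifier.
#' @return list with `sequence` (single string), `keys` (data frame of
#'   `chain`, `resno`, `icode`, `resname`, `res_uid`, one row per
#'   residue in chain order) and `modified` (logical vector).
#' @export
chain_sequence <- function(model, chain_id) {
  stopifnot(inherits(model, "structure_model"))
  if (!chain_id %in% names(model$chain_kind))
    stop("unknown chain '", chain_id, "'; available: ",
         paste(names(model$chain_kind), collapse = ", "), call. = FALSE)
  kind <- model$chain_kind[[chain_id]]
  if (!kind %in% c("rna", "protein"))
    stop("chain '", chain_id, "' is neither RNA nor protein", call. = FALSE)
  res <- model$residues[model$residues$chain == chain_id, , drop = FALSE]
  unknown <- if (kind == "rna") "N" else "X"
  letters <- ifelse(is.na(res$base), unknown, res$base)
  # a protein chain may still carry stray non-aa residues and vice versa
  letters[kind == "rna" & res$kind == "aa"] <- "N"
  letters[kind == "protein" & res$kind == "nt"] <- "X"
  list(sequence = paste(letters, collapse = ""),
       keys = res[, c("chain", "resno", "icode", "resname", "res_uid")],
       modified = res$modified)
}

#' DMS-reactive nitrogen of a nucleotide
#'
#' Dimethyl sulfate methylates N1 of adenine and N3 of cytosine on the
#' Watson-Crick-Franklin face; those two atoms carry the per-nucleotide
#' solvent accessibility used throughout.  Guanosine, uridine and
#' non-nucleotides have no DMS-reactive nitrogen and return `NULL`.
#' Modified nucleosides follow their parent base.
#'
#' @param model a `structure_model`.
#' @param chain,resno,icode residue identifier (author numbering).
#' @return one-row data frame (the atom record) or `NULL`.
#' @export
reactive_atom <- function(model, chain, resno, icode = "") {
  ra <- reactive_atoms(model)
  hit <- ra$chain == chain & ra$resno == resno & ra$icode == icode
  if (!any(hit)) return(NULL)
  ra[hit, , drop = FALSE]
}

#' Reactive-atom table for every A and C residue
#'
#' @param model a `structure_model`.
#' @param chains optional chain subset.
#' @return data frame with one row per A/C residue whose reactive atom
#'   (N1 for A, N3 for C) is present in the model; residues lacking the
#'   atom are omitted.
#' @export
reactive_atoms <- function(model, chains = NULL) {
  stopifnot(inherits(model, "structure_model"))
  res <- model$residues
  if (!is.null(chains)) res <- res[res$chain %in% chains, , drop = FALSE]
  res <- res[!is.na(res$base) & res$base %in% c("A", "C"), , drop = FALSE]
  want <- ifelse(res$base == "A", "N1", "N3")
  at <- model$atoms
  idx <- match(paste(res$res_uid, want), paste(at$res_uid, at$atom))
  out <- cbind(res[, c("res_uid", "chain", "resno", "icode", "resname",
                       "base", "modified")],
               at[idx, c("atom", "element", "x", "y", "z")])
  out <- out[!is.na(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", x$entry_id, "\n")
  cat(sprintf("  %d atoms, %d residues, %d chains\n",
              nrow(x$atoms), nrow(x$residues), length(x$chain_kind)))
  for (ch in names(x$chain_kind)) {
    n <- sum(x$residues$chain == ch)
    cat(sprintf("  chain %-3s %-8s %5d residues\n", ch, x$chain_kind[[ch]], n))
  }
  invisible(x)
}
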