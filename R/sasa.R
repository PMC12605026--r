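# Shrake-Rupley solvent-accessible surface area ------------------------------

# Express coordinates in the molecule's principal-axes frame (deterministic
# sign convention from third moments) so that the sampling lattice co-rotates
# with the molecule: areas become invariant under rigid motion of the input,
# not merely under translation, while staying fully deterministic.
.principal_frame <- function(xyz) {
  if (nrow(xyz) < 3) return(xyz)
  ctr <- colMeans(xyz)
  x0 <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(x0) / nrow(x0), symmetric = TRUE)$vectors
  proj <- x0 %*% ev
  for (k in 1:3) {
    s <- sum(proj[, k]^3)
    if (abs(s) < 1e-8) s <- sum(sign(proj[, k]) * proj[, k]^2 * seq_len(nrow(proj)))
    if (s < 0) proj[, k] <- -proj[, k]
  }
  proj
}

#' Parameters for Shrake-Rupley SASA
#'
#' The accessible surface is traced by the centre of a probe sphere
#' (water, radius 1.4 Angstrom) rolled over the van der Waals surface;
#' each atom's solvent-expanded sphere is sampled with a deterministic
#' golden-spiral lattice and a sample point counts as exposed when it
#' lies outside every other atom's expanded sphere.
#'
#' @param probe_radius probe sphere radius in Angstrom (default 1.4).
#' @param n_points sphere sample count per atom (default 400).  The
#'   relative lattice discretization error scales as ~1/sqrt(n_points).
#' @param vdw_table named vector of van der Waals radii (Angstrom) per
#'   element symbol.  The default is a conventional single-radius set:
#'   C 1.70, N 1.55, O 1.52, P 1.80, S 1.80.
#' @param fallback_radius radius assigned (with a warning) to elements
#'   missing from `vdw_table`; set `NA` to make missing elements an error.
#' @param exclude_solvent drop waters and free ions from the occluder
#'   set (default `TRUE`): solvent should not occlude solvent
#'   accessibility.  Excluded atoms still receive an area of their own.
#' @return a list of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_points = 400,
                        vdw_table = c(C = 1.70, N = 1.55, O = 1.52,
                                      P = 1.80, S = 1.80),
                        fallback_radius = 1.80,
                        exclude_solvent = TRUE) {
  stopifnot(probe_radius > 0, n_points >= 16)
  structure(list(probe_radius = probe_radius, n_points = as.integer(n_points),
                 vdw_table = vdw_table, fallback_radius = fallback_radius,
                 exclude_solvent = exclude_solvent),
            class = "sasa_params")
}

#' Per-atom solvent-accessible surface area
#'
#' @param model a `structure_model`.
#' @param params a [sasa_params()] object.
#' @param chains optional chain subset for which areas are *reported*;
#'   occlusion always considers every (non-solvent) atom of the model.
#' @return data frame of class `sasa_result`: one row per reported atom
#'   with `chain`, `resno`, `icode`, `resname`, `atom`, `element`,
#'   `res_uid` and `sasa` (Angstrom^2); the parameter object is attached
#'   as attribute `params`.
#' @export
shrake_rupley <- function(model, params = sasa_params(), chains = NULL) {
  stopifnot(inherits(model, "structure_model"),
            inherits(params, "sasa_params"))
  at <- model$atoms
  radii <- unname(params$vdw_table[at$element])
  missing_elem <- unique(at$element[is.na(radii)])
  if (length(missing_elem)) {
    if (is.na(params$fallback_radius))
      stop("no van der Waals radius for element(s): ",
           paste(missing_elem, collapse = ", "), call. = FALSE)
    warning("fallback radius ", params$fallback_radius,
            " A used for element(s): ", paste(missing_elem, collapse = ", "),
            call. = FALSE)
    radii[is.na(radii)] <- params$fallback_radius
  }
  occ <- rep(TRUE, nrow(at))
  if (isTRUE(params$exclude_solvent)) {
    solv <- model$residues$kind == "other" &
      toupper(model$residues$resname) %in% .SOLVENT
    occ <- !(at$res_uid %in% model$residues$res_uid[solv])
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  area <- cpp_sasa(.principal_frame(xyz), radii, occ,
                   params$probe_radius, params$n_points)
  out <- at[, c("chain", "resno", "icode", "resname", "atom", "element",
                "res_uid")]
  out$sasa <- area
  if (!is.null(chains)) out <- out[out$chain %in% chains, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- params
  class(out) <- c("sasa_result", class(out))
  out
}

#' Reactive-atom SASA per A/C nucleotide
#'
#' Reduces a per-atom SASA table to one value per adenosine and
#' cytidine: the area of the DMS-reactive nitrogen (N1 of A, N3 of C).
#' Residues whose reactive atom is absent from the model are omitted.
#'
#' @param model a `structure_model`.
#' @param sasa result of [shrake_rupley()] on the same model.
#' @param chains optional chain subset.
#' @return data frame with one row per A/C residue: residue key columns,
#'   `base`, `atom` and `sasa`.
#' @export
reactive_sasa <- function(model, sasa, chains = NULL) {
  ra <- reactive_atoms(model, chains = chains)
  idx <- match(paste(ra$res_uid, ra$atom), paste(sasa$res_uid, sasa$atom))
  if (anyNA(idx))
    stop("sasa table does not cover the reactive atoms; ",
         "was it computed on the same model?", call. = FALSE)
  out <- ra[, c("res_uid", "chain", "resno", "icode", "resname", "base",
                "atom")]
  out$sasa <- sasa$sasa[idx]
  rownames(out) <- NULL
  out
}
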