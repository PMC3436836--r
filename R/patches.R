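# patches: same-property surface patch growing and the 35 structural features

#' Patch-growing configuration
#'
#' @param C Growth tolerance in channel units (tolerance mode: a neighbor
#'   joins when |t1.val - t2.val| < C across the traversed edge).
#' @param mode One of \code{"tolerance"}, \code{"sign"} (same strict sign;
#'   zero-valued triangles form their own patches) or \code{"binary"} (equal
#'   value).
#' @param seed Optional integer; when given, seed triangles are visited in a
#'   seeded random order. When \code{NULL} (default) the canonical
#'   deterministic order (descending |value|, then triangle index) is used.
#' @return A \code{PatchGrowConfig}.
#' @export
patch_config <- function(C = 0, mode = c("tolerance", "sign", "binary"),
                         seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(C >= 0)
  structure(list(C = C, mode = mode, seed = seed), class = "PatchGrowConfig")
}

#' Grow same-property patches on a surface
#'
#' Partitions the (eligible) triangles into edge-connected patches by
#' iterative flood fill: repeatedly take the next unassigned seed triangle and
#' extend its patch across edges whose two triangles satisfy the mode's
#' acceptance predicate.
#'
#' @param mesh A \code{SurfaceMesh}.
#' @param channel Channel name holding the per-triangle values.
#' @param config A \code{\link{patch_config}}.
#' @param eligible Optional logical vector: triangles outside it belong to no
#'   patch (used e.g. to grow hydrophobic patches only over KD >= 0 surface).
#' @return List of patches, each a list with \code{triangle_ids},
#'   \code{area} (sum of member areas), \code{mean_value} (area-weighted) and
#'   \code{sign} (sign of mean_value).
#' @export
grow_patches <- function(mesh, channel, config = patch_config(),
                         eligible = NULL) {
  stopifnot(inherits(mesh, "SurfaceMesh"), inherits(config, "PatchGrowConfig"))
  v <- mesh$channels[[channel]]
  if (is.null(v)) stop("missing channel: ", channel)
  m <- nrow(mesh$triangles)
  if (is.null(eligible)) eligible <- rep(TRUE, m)
  accept <- switch(config$mode,
    tolerance = function(a, b) abs(v[a] - v[b]) < config$C,
    sign = function(a, b) sign(v[a]) == sign(v[b]),
    binary = function(a, b) v[a] == v[b]
  )
  cand <- which(eligible)
  seed_order <- if (!is.null(config$seed)) {
    cand[sample_with_seed(length(cand), config$seed)]
  } else {
    cand[order(-abs(v[cand]), cand)]
  }
  included <- !eligible  # ineligible triangles are never visited
  neigh <- mesh$neighbors
  patches <- list()
  for (s in seed_order) {
    if (included[s]) next
    members <- integer(0)
    stack <- s
    included[s] <- TRUE
    while (length(stack)) {
      t1 <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      members <- c(members, t1)
      for (t2 in neigh[[t1]]) {
        if (!included[t2] && accept(t1, t2)) {
          included[t2] <- TRUE
          stack <- c(stack, t2)
        }
      }
    }
    members <- sort(members)
    ar <- mesh$triangle_area[members]
    mv <- sum(ar * v[members]) / sum(ar)
    patches[[length(patches) + 1]] <- list(
      triangle_ids = members, area = sum(ar), mean_value = mv,
      sign = sign(mv))
  }
  patches
}

sample_with_seed <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(n)
}

#' Areas of the k largest patches
#'
#' Ranks patches by |area| descending and returns \code{area * sign} for the
#' first k, padding with 0 when fewer patches exist.
#'
#' @param patches List of patches from \code{\link{grow_patches}}.
#' @param k Number of slots (default 5).
#' @param signed Carry the patch sign (electrostatics); if FALSE all signs are
#'   +1.
#' @return Numeric vector of length k.
#' @export
top_k_patch_areas <- function(patches, k = 5, signed = TRUE) {
  stopifnot(k >= 1)
  if (!length(patches)) return(numeric(k))
  area <- vapply(patches, `[[`, numeric(1), "area")
  sgn <- if (signed) vapply(patches, `[[`, numeric(1), "sign") else
    rep(1, length(patches))
  ord <- order(-abs(area), seq_along(area))
  out <- (area * sgn)[ord]
  out <- out[seq_len(min(k, length(out)))]
  c(out, numeric(k - length(out)))
}

#' Amino-acid surface propensities
#'
#' Fraction of total surface area contributed by each of the 20 standard
#' amino-acid types (area of triangles attributed to residues of that type
#' over total mesh area).
#'
#' @param mesh A \code{SurfaceMesh} with residue attribution.
#' @return Named numeric vector of length 20 (one-letter codes, table order).
#' @export
surface_propensities <- function(mesh) {
  stopifnot(inherits(mesh, "SurfaceMesh"))
  if (is.null(mesh$triangle_residue)) stop("mesh lacks residue attribution")
  total <- sum(mesh$triangle_area)
  out <- vapply(AA3, function(res)
    sum(mesh$triangle_area[mesh$triangle_residue == res]) / total, numeric(1))
  names(out) <- unname(AA1[AA3])
  if (abs(sum(out) - 1) > 1e-9)
    warning("propensities do not sum to 1 (non-standard residues on surface)")
  out
}

#' Names of the 35 structural features, in fixed column order
#' @return Character vector of length 35.
#' @export
structural_feature_names <- function() {
  c(paste0("elec_patch_area_", 1:5),
    paste0("hyd_patch_area_", 1:5),
    paste0("hbond_patch_area_", 1:5),
    paste0("prop_", unname(AA1[AA3])))
}

#' Compute the 35 structural features of a mapped surface
#'
#' Electrostatic patches are grown by sign connectivity over the whole
#' surface (signed areas, ranked by |area|); hydrophobic patches by value
#' tolerance restricted to triangles with KD value >= \code{hyd_min};
#' hydrogen-bond patches as connected components of value-1 triangles. The
#' five largest |areas| per category plus the 20 amino-acid surface
#' propensities give 35 features.
#'
#' @param mesh A \code{SurfaceMesh} with the three channels mapped.
#' @param elec_channel,hyd_channel,hbond_channel Channel names.
#' @param hyd_C Tolerance constant for hydrophobic patch growth, KD units
#'   (default 1.5).
#' @param hyd_min Minimum KD value for a triangle to take part in hydrophobic
#'   patches (default 0).
#' @return Named numeric vector of length 35 (see
#'   \code{\link{structural_feature_names}}).
#' @export
structural_features <- function(mesh, elec_channel = "elec",
                                hyd_channel = "hyd", hbond_channel = "hbond",
                                hyd_C = 1.5, hyd_min = 0) {
  stopifnot(inherits(mesh, "SurfaceMesh"))
  for (ch in c(elec_channel, hyd_channel, hbond_channel))
    if (is.null(mesh$channels[[ch]])) stop("missing channel: ", ch)
  elec <- grow_patches(mesh, elec_channel, patch_config(mode = "sign"))
  hydv <- mesh$channels[[hyd_channel]]
  hyd <- grow_patches(mesh, hyd_channel,
                      patch_config(C = hyd_C, mode = "tolerance"),
                      eligible = hydv >= hyd_min)
  hbv <- mesh$channels[[hbond_channel]]
  hb <- grow_patches(mesh, hbond_channel, patch_config(mode = "binary"),
                     eligible = hbv == 1)
  out <- c(top_k_patch_areas(elec, 5, signed = TRUE),
           top_k_patch_areas(hyd, 5, signed = FALSE),
           top_k_patch_areas(hb, 5, signed = FALSE),
           surface_propensities(mesh))
  names(out) <- structural_feature_names()
  out
}
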