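#' @name habitat
#' @title Site-level habitat covariates
#' @description Three covariate classes measured around each camera:
#'   seabird burrow density from the point-centre-quarter (PCQ) method,
#'   vegetation structural complexity from a touch-pole, and visually
#'   estimated floristic covers.
NULL

#' Point-centre-quarter burrow density for one sample point
#'
#' The classic plotless estimator: with `mu` the mean of the four
#' quadrant nearest-burrow distances (metres), density is `1/mu^2` per
#' square metre, scaled to burrows per hectare. Quadrants with no burrow
#' within the search radius contribute the truncation distance to `mu`
#' (a conservative substitution that biases density down); a point with
#' no burrow in any quadrant is assigned density 0. The alternative
#' `"pollard"` estimator `12 / (pi * sum(d^2))` is unbiased per point for
#' a Poisson burrow field; `"cottam"` (the default, the field's usual
#' formula) is upward-biased at a single point with only four distances,
#' so treat per-site values as a relative index rather than an absolute
#' density.
#'
#' @param distances four quadrant distances in metres (NE, NW, SE, SW);
#'   NA = no burrow within the search radius.
#' @param truncation search radius in metres (default 40).
#' @param method `"cottam"` (1/mu^2) or `"pollard"`.
#' @return Density in burrows per hectare. The number of empty quadrants
#'   is attached as attribute `"n_empty"`.
#' @export
pcq_density <- function(distances, truncation = 40,
                        method = c("cottam", "pollard")) {
  method <- match.arg(method)
  if (length(distances) != 4) stop("expected four quadrant distances")
  if (any(distances <= 0, na.rm = TRUE)) {
    stop("zero or negative distance: a burrow cannot be at the point")
  }
  if (any(distances > truncation, na.rm = TRUE)) {
    stop("distance beyond the truncation radius")
  }
  n_empty <- sum(is.na(distances))
  if (n_empty == 4) {
    return(structure(0, n_empty = 4L))
  }
  d <- ifelse(is.na(distances), truncation, distances)
  per_m2 <- if (method == "cottam") 1 / mean(d)^2
            else 12 / (pi * sum(d^2))
  structure(per_m2 * 1e4, n_empty = as.integer(n_empty))
}

#' Field-level PCQ density from pooled distances
#'
#' Pools quadrant distances across all sample points before applying the
#' point-centre-quarter formula (`1 / mean(d)^2`), the form in which the
#' estimator is consistent for a homogeneous Poisson field. Empty
#' quadrants contribute the truncation distance.
#'
#' @param pcq PCQ table (site_id, quadrant, distance_m, ...) as produced
#'   by [simulate_pcq()].
#' @param truncation search radius in metres.
#' @return Density in burrows per hectare.
#' @export
pcq_density_pooled <- function(pcq, truncation = 40) {
  d <- pcq$distance_m
  d[is.na(d)] <- truncation
  if (any(d <= 0)) stop("zero or negative distance in PCQ table")
  1e4 / mean(d)^2
}

#' Per-site PCQ densities from a long-format table
#'
#' @param pcq data frame (site_id, quadrant, distance_m, optionally
#'   burrow_type).
#' @param truncation search radius in metres.
#' @param method passed to [pcq_density()].
#' @return Data frame (site_id, \[burrow_type,\] density_ha, n_empty).
#' @export
pcq_density_by_site <- function(pcq, truncation = 40,
                                method = c("cottam", "pollard")) {
  method <- match.arg(method)
  by_cols <- intersect(c("site_id", "burrow_type"), names(pcq))
  split_key <- interaction(pcq[by_cols], drop = TRUE)
  rows <- lapply(split(pcq, split_key), function(g) {
    if (nrow(g) != 4) {
      stop("site ", g$site_id[1], " does not have exactly 4 quadrants")
    }
    dens <- pcq_density(g$distance_m, truncation = truncation,
                        method = method)
    cbind(g[1, by_cols, drop = FALSE],
          data.frame(density_ha = as.numeric(dens),
                     n_empty = attr(dens, "n_empty")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$site_id), , drop = FALSE]
}

#' Structural complexity from a touch-pole survey
#'
#' Mean over the site's eight poles of the summed vegetation touches
#' within a height band. The default band, 100-400 mm, captures
#' near-ground complexity.
#'
#' @param touches matrix or data frame: 8 poles (rows) x 10 height bands
#'   (columns; band j covers (100(j-1), 100j\] mm), entries 0-10; or a
#'   long data frame with columns `pole`, `band`, `touches`.
#' @param band height range in mm, `c(low, high)`, aligned to 100-mm
#'   boundaries within 0-1000.
#' @return Mean summed touches per pole within the band.
#' @export
structural_complexity <- function(touches, band = c(100, 400)) {
  if (is.data.frame(touches) && all(c("pole", "band") %in% names(touches))) {
    m <- matrix(0, 8, 10)
    m[cbind(touches$pole, touches$band)] <- touches$touches
    touches <- m
  }
  touches <- as.matrix(touches)
  if (nrow(touches) != 8 || ncol(touches) != 10) {
    stop("expected 8 poles x 10 height bands")
  }
  if (any(touches < 0 | touches > 10)) stop("touches must be in [0,10]")
  if (band[1] < 0 || band[2] > 1000 || band[1] >= band[2] ||
      any(band %% 100 != 0)) {
    stop("band must align to 100-mm intervals within 0-1000 mm")
  }
  cols <- (band[1] / 100 + 1):(band[2] / 100)
  mean(rowSums(touches[, cols, drop = FALSE]))
}

#' Assemble the site covariate table
#'
#' Joins per-site PCQ burrow densities (by burrow type), touch-pole
#' complexity and floristic covers into one row per site with the
#' covariate names used by the candidate models: `Poa`, `Tetra`, `Rhag`,
#' `Disphyma`, `Other` (% covers), `C_gt1m` (% cover above 1 m, visual),
#' `C10_40` (mean touches 100-400 mm), `Atden` (shearwater burrows/ha),
#' `Emden` (penguin burrows/ha) and `BD = Atden + Emden`.
#'
#' @param pcq long PCQ table (site_id, quadrant, burrow_type,
#'   distance_m).
#' @param poles long pole table (site_id, pole, band, touches).
#' @param covers cover table (site_id, Poa, Tetra, Rhag, Disphyma, Other,
#'   C_gt1m).
#' @param truncation PCQ search radius (m).
#' @param pcq_method PCQ estimator; see [pcq_density()].
#' @param standardize if TRUE, z-score the numeric covariates (recorded
#'   in attribute `"standardized"`).
#' @return Data frame, one row per site (outer join; sites missing a
#'   survey get NA in the affected columns, with a warning).
#' @export
assemble_covariates <- function(pcq, poles, covers, truncation = 40,
                                pcq_method = c("cottam", "pollard"),
                                standardize = FALSE) {
  pcq_method <- match.arg(pcq_method)
  if (anyDuplicated(covers$site_id)) stop("duplicate site rows in covers")

  dens <- pcq_density_by_site(pcq, truncation = truncation,
                              method = pcq_method)
  at <- dens[dens$burrow_type == "shearwater", c("site_id", "density_ha")]
  em <- dens[dens$burrow_type == "penguin", c("site_id", "density_ha")]
  names(at)[2] <- "Atden"
  names(em)[2] <- "Emden"

  c10 <- do.call(rbind, lapply(split(poles, poles$site_id), function(g) {
    data.frame(site_id = g$site_id[1],
               C10_40 = structural_complexity(g, band = c(100, 400)),
               stringsAsFactors = FALSE)
  }))

  out <- merge(covers, c10, by = "site_id", all = TRUE)
  out <- merge(out, at, by = "site_id", all = TRUE)
  out <- merge(out, em, by = "site_id", all = TRUE)
  out$Atden[is.na(out$Atden) & out$site_id %in% dens$site_id] <- 0
  out$Emden[is.na(out$Emden) & out$site_id %in% dens$site_id] <- 0
  out$BD <- out$Atden + out$Emden

  incomplete <- !complete.cases(out)
  if (any(incomplete)) {
    warning(sum(incomplete), " site(s) missing one or more surveys: ",
            paste(head(out$site_id[incomplete], 5), collapse = ", "))
  }
  if (standardize) {
    num <- setdiff(names(out), "site_id")
    out[num] <- lapply(out[num], function(x) as.numeric(scale(x)))
  }
  attr(out, "standardized") <- standardize
  attr(out, "pcq_method") <- pcq_method
  rownames(out) <- NULL
  out
}

#' Pairwise collinearity screen
#'
#' @param covariates covariate table from [assemble_covariates()].
#' @param threshold absolute correlation above which a pair is flagged
#'   (default 0.55).
#' @return Data frame of flagged pairs (var1, var2, r), with the maximum
#'   absolute correlation as attribute `"max_abs_r"`.
#' @export
screen_collinearity <- function(covariates, threshold = 0.55) {
  num <- covariates[vapply(covariates, is.numeric, logical(1))]
  cm <- cor(as.matrix(num), use = "pairwise.complete.obs")
  cm[!lower.tri(cm)] <- NA
  idx <- which(abs(cm) > threshold, arr.ind = TRUE)
  out <- data.frame(var1 = rownames(cm)[idx[, 1]],
                    var2 = colnames(cm)[idx[, 2]],
                    r = cm[idx], stringsAsFactors = FALSE)
  attr(out, "max_abs_r") <- max(abs(cm), na.rm = TRUE)
  out
}
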