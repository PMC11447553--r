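# Correlation of local composition with local thickness, and
# Gaussian-mixture identification of thickness domains ("larger" vs
# "smaller") with their mean tail compositions.

#' Pool thickness and composition maps into a per-cell table
#'
#' Joins cells valid in both maps; rows pool over multiple frame pairs.
#'
#' @param thickness_maps `sc_gridmap` (or list) of kind thickness.
#' @param composition_maps matching `sc_gridmap` (or list) of kind
#'   composition.
#' @return data.frame: `thickness` plus one fraction column per tail type.
#' @export
pool_grid_data <- function(thickness_maps, composition_maps) {
  if (inherits(thickness_maps, "sc_gridmap")) thickness_maps <- list(thickness_maps)
  if (inherits(composition_maps, "sc_gridmap")) composition_maps <- list(composition_maps)
  stopifnot(length(thickness_maps) == length(composition_maps))
  rows <- mapply(function(tm, cm) {
    ok <- tm$valid & cm$valid
    if (!any(ok)) return(NULL)
    df <- data.frame(thickness = tm$values[ok])
    for (tt in TAIL_TYPES) df[[tt]] <- cm$values[, , tt][ok]
    df
  }, thickness_maps, composition_maps, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no cells valid in both maps")
  out
}

#' Correlation of local composition with local thickness
#'
#' Pearson r and Spearman rho between the local bilayer thickness and the
#' local fraction of each tail type over pooled valid grid cells. Positive
#' r means the fraction rises with thickness. Zero variance in either
#' variable yields NA with a flag.
#'
#' @param data pooled table from [pool_grid_data()] (or any data.frame
#'   with a `thickness` column and one column per tail type).
#' @return data.frame: `tail_type`, `pearson_r`, `spearman_rho`, `n`,
#'   `degenerate`.
#' @export
thickness_composition_correlation <- function(data) {
  if (nrow(data) < 10) stop("need at least 10 paired observations")
  th <- data$thickness
  out <- lapply(TAIL_TYPES, function(tt) {
    fr <- data[[tt]]
    degenerate <- stats::sd(th) == 0 || stats::sd(fr) == 0
    data.frame(tail_type = tt,
               pearson_r = if (degenerate) NA_real_ else stats::cor(th, fr),
               spearman_rho = if (degenerate) NA_real_ else
                 stats::cor(th, fr, method = "spearman"),
               n = length(fr), degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gaussian-mixture domain identification
#'
#' Fits a two-component full-covariance Gaussian mixture to the joint
#' (thickness, four tail fractions) vectors, standardized per coordinate,
#' and labels the component with the greater mean thickness "larger". The
#' summary reports each domain's mean thickness and mean tail composition
#' as percentages, next to the mixture-wide average — the layout of the
#' study's domain-composition table.
#'
#' @param data pooled table from [pool_grid_data()].
#' @param k number of mixture components (fixed at 2: the larger/smaller
#'   thickness dichotomy).
#' @param seed RNG seed (the EM initialization used here is deterministic;
#'   the seed guards any tie-breaking).
#' @param min_gap mean-thickness gap (nm) under which the fit is flagged
#'   `no_separation`.
#' @return object of class `sc_domains`: `summary` data.frame (rows
#'   larger / smaller / mixture average), per-point `labels`, component
#'   `weights`, `no_separation` flag, and the fitted `model`.
#' @export
gmm_domains <- function(data, k = 2, seed = 1, min_gap = 0.1) {
  if (nrow(data) < 2 * k) stop("need at least 2k points")
  # fractions sum to 1, so one is dropped from the feature space to keep
  # the full covariance nonsingular; summaries still report all four
  feats <- as.matrix(data[, c("thickness", TAIL_TYPES[1:3])])
  mu <- colMeans(feats); sdv <- apply(feats, 2, stats::sd)
  sdv[sdv == 0] <- 1
  std <- sweep(sweep(feats, 2, mu), 2, sdv, "/")
  set.seed(seed)
  # full-covariance EM with model-based hierarchical initialization
  # (deterministic, so no random restarts are needed)
  run_em <- function(x) {
    hcinit <- mclust::hcVVV(x)
    z0 <- mclust::unmap(as.vector(mclust::hclass(hcinit, k)))
    ms <- mclust::mstepVVV(x, z0)
    mclust::emVVV(x, parameters = ms$parameters)
  }
  fit <- tryCatch(run_em(std), error = function(e) list(z = NA))
  if (is.null(fit$z) || any(!is.finite(fit$z))) {
    # duplicated grid cells can make a component's covariance singular;
    # restart on imperceptibly jittered coordinates
    fit <- tryCatch(run_em(std + stats::rnorm(length(std), 0, 1e-6)),
                    error = function(e) list(z = NA))
  }
  if (is.null(fit$z) || any(!is.finite(fit$z)))
    stop("mixture fit failed (degenerate covariance)")
  cls <- mclust::map(fit$z)
  mth <- tapply(data$thickness, cls, mean)
  larger <- as.integer(names(mth)[which.max(mth)])
  lab <- ifelse(cls == larger, "larger", "smaller")
  comp_means <- function(sel) {
    c(thickness = mean(data$thickness[sel]),
      vapply(TAIL_TYPES, function(tt) mean(data[[tt]][sel]), numeric(1)))
  }
  rows <- rbind(larger = comp_means(lab == "larger"),
                smaller = comp_means(lab == "smaller"),
                `mixture average` = comp_means(rep(TRUE, nrow(data))))
  summary <- data.frame(
    domain = rownames(rows),
    CER_acyl_pct = round(100 * rows[, "CER_acyl"]),
    CER_sph_pct = round(100 * rows[, "CER_sph"]),
    CHOL_pct = round(100 * rows[, "CHOL"]),
    FFA_pct = round(100 * rows[, "FFA"]),
    thickness_nm = round(rows[, "thickness"], 2),
    weight = c(mean(lab == "larger"), mean(lab == "smaller"), 1),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = summary, labels = lab,
                 means_raw = rows,
                 weights = c(larger = mean(lab == "larger"),
                             smaller = mean(lab == "smaller")),
                 no_separation = abs(diff(range(mth))) < min_gap,
                 model = fit),
            class = "sc_domains")
}

#' @export
print.sc_domains <- function(x, ...) {
  cat("<sc_domains> two-component Gaussian mixture on (thickness, composition)\n")
  if (x$no_separation) cat("  flag: no separation (mean-thickness gap < threshold)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
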