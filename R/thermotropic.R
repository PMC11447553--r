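# Thermotropic structural metrics: nematic order parameter S2 per chain
# class, carbon-hydrogen order parameter S_CH, normalized lipid area (NLA,
# CHOL weighted 1.9), membrane thickness from the water density profile,
# 5-degC block averaging, and continuous two-regime (hinge) fitting.

# S2 classification bands for lamellar systems
S2_ORDERED_MIN <- 0.8
S2_ISOTROPIC_MAX <- 0.3

#' Principal-axis director of a chain section
#'
#' Dominant principal axis of the bead coordinates (unit vector, sign
#' arbitrary) — robust to mid-chain kinks, unlike the end-to-end vector.
#'
#' @param coords n x 3 bead coordinates.
#' @return unit length-3 vector.
#' @export
chain_director <- function(coords) {
  if (nrow(coords) < 2) stop("need at least 2 beads")
  cc <- sweep(coords, 2, colMeans(coords))
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  v <- ev$vectors[, 1]
  v / sqrt(sum(v^2))
}

#' Nematic order parameter from directors
#'
#' `S2` is the largest eigenvalue of `Q = mean over chains of
#' (3 u u^T - I)/2`. A value of 1 means all tails point in the same
#' direction; values near 0 indicate isotropic disorder. With `groups`
#' (e.g. leaflet indices), S2 is computed per group and averaged.
#'
#' @param directors n x 3 matrix of unit chain directors.
#' @param groups optional grouping vector of length n.
#' @return scalar S2.
#' @export
nematic_s2 <- function(directors, groups = NULL) {
  one <- function(U) {
    if (nrow(U) < 1) return(NA_real_)
    Q <- matrix(0, 3, 3)
    for (i in seq_len(nrow(U))) {
      u <- U[i, ]
      Q <- Q + (3 * tcrossprod(u) - diag(3)) / 2
    }
    Q <- Q / nrow(U)
    max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
  }
  if (is.null(groups)) return(one(directors))
  vals <- vapply(split(seq_len(nrow(directors)), groups),
                 function(ii) one(directors[ii, , drop = FALSE]), numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Extract per-chain 12-carbon sections
#'
#' Carbons 4..15 counted from the head-proximal end (clamped to the chain;
#' chains shorter than 12 carbons use the full chain with a warning) —
#' chosen to avoid the interdigitated region between leaflets and the
#' headgroup-adjacent part of the tail.
#'
#' @param frame,topology as elsewhere.
#' @param section integer carbon index window (default 4:15).
#' @param roles chain roles to include (default the S2-relevant classes:
#'   acyl, sphingosine, fatty).
#' @return list with `directors` (n x 3), `tail_type`, `lipid_id`.
#' @export
chain_sections <- function(frame, topology, section = 4:15,
                           roles = c("acyl", "sphingosine", "fatty")) {
  topo <- topology
  sel <- topo$species != "WATER" & !topo$is_head & topo$chain_role %in% roles
  sub <- topo[sel, ]
  co <- frame$coords[sel, , drop = FALSE]
  idx <- split(seq_len(nrow(sub)), paste(sub$lipid_id, sub$chain_role))
  short <- FALSE
  dirs <- matrix(NA_real_, length(idx), 3)
  ttype <- character(length(idx)); lid <- integer(length(idx))
  for (q in seq_along(idx)) {
    ii <- idx[[q]]
    n <- length(ii)
    use <- section[section <= n]
    if (length(use) < length(section)) { short <- TRUE; use <- seq_len(n) }
    dirs[q, ] <- chain_director(co[ii[use], , drop = FALSE])
    ttype[q] <- switch(sub$chain_role[ii[1]], acyl = "CER_acyl",
                       sphingosine = "CER_sph", fatty = "FFA",
                       sterol = "CHOL")
    lid[q] <- sub$lipid_id[ii[1]]
  }
  if (short)
    warning("chain(s) shorter than the requested section; used full chain")
  list(directors = dirs, tail_type = ttype, lipid_id = lid)
}

#' Per-class nematic order of a system frame
#'
#' S2 per chain class (FFA, CER acyl, CER sphingosine) computed from the
#' 12-carbon-section directors over the inner leaflets (all leaflets
#' except the two outermost) and averaged across leaflets.
#'
#' @param frame,topology,leaflets as elsewhere.
#' @param section carbon window (default 4:15).
#' @param inner_only drop the two outermost leaflets (default TRUE).
#' @return named numeric: S2 for FFA, CER_acyl, CER_sph.
#' @export
s2_by_class <- function(frame, topology, leaflets, section = 4:15,
                        inner_only = TRUE) {
  cs <- chain_sections(frame, topology, section)
  ti <- tail_instances(frame, topology, leaflets)
  key <- paste(ti$lipid_id, ti$tail_type)
  leaf <- stats::setNames(ti$leaflet, key)[paste(cs$lipid_id, cs$tail_type)]
  keep <- rep(TRUE, length(leaf))
  if (inner_only)
    keep <- leaf > 1 & leaf < leaflets$n_leaflets & !is.na(leaf)
  out <- vapply(c("FFA", "CER_acyl", "CER_sph"), function(tt) {
    ii <- which(cs$tail_type == tt & keep)
    if (length(ii) < 2) return(NA_real_)
    nematic_s2(cs$directors[ii, , drop = FALSE], groups = leaf[ii])
  }, numeric(1))
  out
}

#' Carbon-hydrogen order parameter profile
#'
#' `S_CH = (1/2) <3 cos^2 theta - 1>` where theta is the angle between
#' each C-H bond vector and the bilayer normal (z). The average runs over
#' both hydrogens of each carbon and all chains of a class; values range
#' from -0.5 (C-H perpendicular to the normal) to 1 (parallel).
#'
#' @param hydrogens table from [attach_pseudo_hydrogens()].
#' @param by_class split by `tail_type` (default TRUE).
#' @return data.frame: `tail_type` (if requested), `carbon_index`, `s_ch`,
#'   `n_vectors`.
#' @export
sch_profile <- function(hydrogens, by_class = TRUE) {
  if (!nrow(hydrogens)) stop("no C-H vectors supplied")
  if (any(!is.finite(hydrogens$hz)))
    stop("missing H vector on carbon ",
         hydrogens$carbon_index[which(!is.finite(hydrogens$hz))[1]])
  grp <- if (by_class) paste(hydrogens$tail_type, hydrogens$carbon_index)
         else as.character(hydrogens$carbon_index)
  agg <- tapply(hydrogens$hz^2, grp, function(c2) 0.5 * (3 * mean(c2) - 1))
  cnt <- tapply(hydrogens$hz, grp, length)
  if (by_class) {
    parts <- strsplit(names(agg), " ")
    out <- data.frame(tail_type = vapply(parts, `[`, "", 1),
                      carbon_index = as.integer(vapply(parts, `[`, "", 2)),
                      s_ch = as.numeric(agg), n_vectors = as.integer(cnt),
                      stringsAsFactors = FALSE)
    out[order(out$tail_type, out$carbon_index), ]
  } else {
    out <- data.frame(carbon_index = as.integer(names(agg)),
                      s_ch = as.numeric(agg), n_vectors = as.integer(cnt))
    out[order(out$carbon_index), ]
  }
}

#' Normalized lipid area
#'
#' Weighted tail count per lateral area: CER acyl, CER sphingosine and FFA
#' tails weigh 1, CHOL weighs 1.9 (its larger cross-section), divided by
#' Lx * Ly. The reciprocal (area per weighted tail) is also reported.
#'
#' @param tail_types character vector of the leaflet's tail types, or a
#'   named count vector over `CER_acyl`, `CER_sph`, `CHOL`, `FFA`.
#' @param lx,ly lateral box lengths in nm.
#' @return list `nla` (nm^-2) and `area_per_tail` (nm^2).
#' @export
normalized_lipid_area <- function(tail_types, lx, ly) {
  if (lx <= 0 || ly <= 0) stop("area must be positive")
  cnt <- if (!is.null(names(tail_types)) && is.numeric(tail_types))
    tail_types else table(tail_types)
  n <- stats::setNames(numeric(4), TAIL_TYPES)
  n[names(cnt)] <- as.numeric(cnt)
  if (sum(n) == 0) stop("empty leaflet")
  weighted <- n["CER_acyl"] + n["CER_sph"] + n["FFA"] + 1.9 * n["CHOL"]
  nla <- as.numeric(weighted) / (lx * ly)
  list(nla = nla, area_per_tail = 1 / nla)
}

#' Water mass-density profile along the bilayer normal
#'
#' @param frame,topology as elsewhere.
#' @param bin z bin width in nm (default 0.1).
#' @return data.frame `z` (bin centers), `density` (amu nm^-3).
#' @export
water_density_profile <- function(frame, topology, bin = 0.1) {
  sel <- topology$species == "WATER"
  if (!any(sel)) stop("no water in system")
  z <- frame$coords[sel, 3]
  m <- topology$mass[sel]
  breaks <- seq(0, frame$box[3] + bin, by = bin)
  idx <- findInterval(z, breaks, rightmost.closed = TRUE)
  dens <- numeric(length(breaks) - 1)
  tb <- rowsum(m, idx)
  keep <- as.integer(rownames(tb))
  ok <- keep >= 1 & keep <= length(dens)
  dens[keep[ok]] <- tb[ok] / (frame$box[1] * frame$box[2] * bin)
  data.frame(z = (breaks[-1] + breaks[-length(breaks)]) / 2, density = dens)
}

#' Membrane thickness from the water density profile
#'
#' The bulk water density is taken as the mean over the outermost
#' `bulk_window` of each water slab; on each side the interface is the z
#' at which the profile first drops to half the bulk value (linear
#' interpolation), and the thickness is the distance between the two
#' inner interfaces.
#'
#' @param profile data.frame `z`, `density` from [water_density_profile()].
#' @param bulk_window width of the bulk reference region per side, nm.
#' @return thickness in nm.
#' @export
membrane_thickness <- function(profile, bulk_window = 0.5) {
  z <- profile$z; d <- profile$density
  nz <- which(d > 0)
  if (!length(nz)) stop("profile contains no water")
  bin <- stats::median(diff(z))
  nb <- max(1L, round(bulk_window / bin))
  lo_slab <- nz[1]:min(nz[1] + nb - 1L, length(d))
  hi_slab <- max(nz[length(nz)] - nb + 1L, 1L):nz[length(nz)]
  bulk_lo <- mean(d[lo_slab]); bulk_hi <- mean(d[hi_slab])
  mid <- round((nz[1] + nz[length(nz)]) / 2)
  if (all(d[max(1, mid - 2):min(length(d), mid + 2)] > 0.5 * min(bulk_lo, bulk_hi)))
    stop("water appears on one side only (no interior dry region)")
  cross_inner <- function(direction, bulk) {
    # from the dry interior, move outward to the first bin at or above
    # half bulk; the interface is interpolated on its inner flank, which
    # is robust to density noise farther out in the slab
    half <- bulk / 2
    i <- mid
    while (i >= 1 && i <= length(d) && d[i] < half) i <- i + direction
    if (i < 1 || i > length(d)) stop("no half-bulk crossing found")
    i_in <- i - direction
    f <- (half - d[i_in]) / (d[i] - d[i_in])
    z[i_in] + f * (z[i] - z[i_in])
  }
  z_bot <- cross_inner(-1L, bulk_lo)
  z_top <- cross_inner(+1L, bulk_hi)
  abs(z_top - z_bot)
}

#' Block-average a temperature-tagged series
#'
#' Metrics are averaged within half-open temperature blocks
#' `[T0, T0 + block)` of width `block` degC (default 5). Empty blocks are
#' omitted with a warning.
#'
#' @param data data.frame with a temperature column plus numeric metrics.
#' @param temp_col name of the temperature column (default "T").
#' @param block block width in degC.
#' @return data.frame: `block_T` (block center), `n_frames`, block means
#'   of every other numeric column.
#' @export
block_average <- function(data, temp_col = "T", block = 5) {
  Tv <- data[[temp_col]]
  if (is.null(Tv)) stop("no temperature column '", temp_col, "'")
  b0 <- floor(Tv / block) * block
  metrics <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], temp_col)
  lev <- sort(unique(b0))
  full <- seq(min(lev), max(lev), by = block)
  if (length(full) > length(lev))
    warning(length(full) - length(lev), " empty block(s) omitted")
  out <- data.frame(block_T = lev + block / 2,
                    n_frames = as.integer(table(factor(b0, levels = lev))))
  for (m in metrics)
    out[[m]] <- as.numeric(tapply(data[[m]], factor(b0, levels = lev),
                                  mean, na.rm = TRUE))
  out
}

#' Continuous two-regime (hinge) fit
#'
#' Piecewise-linear least squares with a continuity constraint at the
#' breakpoint; the breakpoint is found by exhaustive search over interior
#' block boundaries with at least 3 points per segment. When the SSE
#' improvement over a single line is below `min_improvement`, the series
#' is flagged as having no transition.
#'
#' @param x block temperatures (ascending).
#' @param y metric values.
#' @param block block width used to lay boundaries (default 5 degC).
#' @param min_improvement relative SSE improvement threshold (default 0.05).
#' @return object of class `sc_tworegime`: `breakpoint`, `slopes`
#'   (below/above), `sse`, `sse_single`, `improvement`, `no_transition`.
#' @export
two_regime_fit <- function(x, y, block = 5, min_improvement = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 6) stop("need at least 6 blocks for a two-regime fit")
  o <- order(x); x <- x[o]; y <- y[o]
  cand <- seq(ceiling(min(x) / block) * block,
              floor(max(x) / block) * block, by = block)
  cand <- cand[vapply(cand, function(c0) sum(x < c0) >= 3 && sum(x >= c0) >= 3,
                      logical(1))]
  if (!length(cand)) stop("no admissible breakpoint with 3 points per segment")
  fit1 <- stats::lm.fit(cbind(1, x), y)
  sse1 <- sum(fit1$residuals^2)
  best <- NULL
  for (c0 in cand) {
    X <- cbind(1, x - c0, pmax(x - c0, 0))
    f <- stats::lm.fit(X, y)
    sse <- sum(f$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(c0 = c0, sse = sse, coef = f$coefficients)
  }
  slopes <- c(below = unname(best$coef[2]),
              above = unname(best$coef[2] + best$coef[3]))
  improvement <- 1 - best$sse / max(sse1, .Machine$double.eps)
  # a single line already at numerical zero residual leaves nothing to gain
  if (sse1 <= 1e-12 * max(sum(y^2), 1)) improvement <- 0
  structure(list(breakpoint = best$c0, slopes = slopes, sse = best$sse,
                 sse_single = sse1, improvement = improvement,
                 no_transition = improvement < min_improvement,
                 coefficients = best$coef),
            class = "sc_tworegime")
}

#' @export
print.sc_tworegime <- function(x, ...) {
  if (x$no_transition) {
    cat(sprintf("<sc_tworegime> no transition (SSE improvement %.1f%% < threshold)\n",
                100 * x$improvement))
  } else {
    cat(sprintf("<sc_tworegime> breakpoint %.1f degC; slopes %.4g (below), %.4g (above); SSE %.4g\n",
                x$breakpoint, x$slopes["below"], x$slopes["above"], x$sse))
  }
  invisible(x)
}

#' Thermotropic metric series of a temperature sweep
#'
#' Per frame: S2 per chain class over the inner leaflets, NLA per leaflet
#' (averaged) with its reciprocal, and membrane thickness from the water
#' density profile; then 5-degC block averaging.
#'
#' @param system temperature-tagged `sc_system` (e.g. from
#'   [make_temperature_sweep()]).
#' @param section carbon window for S2.
#' @param block block width, degC; `NULL` skips block averaging.
#' @return data.frame per block (or per frame when `block = NULL`):
#'   `block_T`/`T`, `S2_FFA`, `S2_acyl`, `S2_sph`, `NLA`, `NLA_reciprocal`,
#'   `thickness`.
#' @export
thermo_series <- function(system, section = 4:15, block = 5) {
  topo <- system$topology
  rows <- lapply(system$frames, function(fr) {
    lf <- assign_leaflets(fr, topo)
    s2 <- s2_by_class(fr, topo, lf, section = section)
    ti <- tail_instances(fr, topo, lf)
    nlas <- vapply(split(ti$tail_type, ti$leaflet), function(tt)
      normalized_lipid_area(tt, fr$box[1], fr$box[2])$nla, numeric(1))
    th <- membrane_thickness(water_density_profile(fr, topo))
    data.frame(T = fr$tag, S2_FFA = s2[["FFA"]], S2_acyl = s2[["CER_acyl"]],
               S2_sph = s2[["CER_sph"]], NLA = mean(nlas),
               NLA_reciprocal = 1 / mean(nlas), thickness = th)
  })
  df <- do.call(rbind, rows)
  if (is.null(block)) return(df)
  block_average(df, block = block)
}
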