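# Grid-based local bilayer thickness and composition of the central
# bilayer. A G x G grid is drawn across the membrane plane; at each grid
# point the lipids within a periodic in-plane radius are isolated, a
# head-bead mass-density histogram along z is built, and the thickness is
# the distance between the two peaks flanking the central-bilayer midplane.

new_gridmap <- function(x, y, values, valid, kind) {
  structure(list(x = x, y = y, values = values, valid = valid, kind = kind),
            class = "sc_gridmap")
}

#' @export
print.sc_gridmap <- function(x, ...) {
  cat(sprintf("<sc_gridmap> %s, %d x %d cells, %.0f%% valid\n", x$kind,
              length(x$x), length(x$y), 100 * mean(x$valid)))
  invisible(x)
}

# refine a histogram peak position by mass-weighted centroid of the peak
# bin and its neighbors
refine_peak <- function(mids, dens, i) {
  lo <- max(1, i - 1); hi <- min(length(dens), i + 1)
  sum(mids[lo:hi] * dens[lo:hi]) / sum(dens[lo:hi])
}

# peaks of a z-density vector flanking a midplane; returns c(lo, hi) or NULL
flanking_peaks <- function(mids, dens, midplane, min_frac = 0.05) {
  sm <- as.numeric(stats::filter(dens, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- dens[is.na(sm)] / 3
  pk <- local_maxima(c(0, sm, 0)) - 1L
  pk <- pk[sm[pk] >= min_frac * max(sm)]
  if (length(pk) < 2) return(NULL)
  pz <- vapply(pk, function(i) refine_peak(mids, dens, i), numeric(1))
  below <- pz[pz < midplane]; bel_i <- pk[pz < midplane]
  above <- pz[pz >= midplane]; abv_i <- pk[pz >= midplane]
  if (!length(below) || !length(above)) return(NULL)
  c(below[which.max(below)], above[which.min(above)])
}

#' Local bilayer thickness map
#'
#' At each of G x G grid points, lipids with whole-lipid center of mass
#' within `radius` (periodic x-y distance) are isolated; their head-bead
#' mass-density histogram along z (bin width `bin`) is scanned for the two
#' peaks closest to and flanking the central-bilayer midplane, and the
#' thickness is the peak separation. Cells with fewer than `min_lipids`
#' contributors or without two flanking peaks are masked.
#'
#' @param frame an `sc_frame`.
#' @param topology an `sc_topology`.
#' @param leaflets an `sc_leaflets`; its `central_bilayer` pair defines the
#'   midplane (mean of the two central head-plane peaks).
#' @param G grid size per side (default 50).
#' @param radius neighborhood radius in nm (default 0.8).
#' @param bin z histogram bin width in nm (default 0.1).
#' @param min_lipids mask threshold (default 3).
#' @return `sc_gridmap` with `values` a G x G matrix of thickness (nm).
#' @export
thickness_map <- function(frame, topology, leaflets, G = 50, radius = 0.8,
                          bin = 0.1, min_lipids = 3) {
  if (is.null(leaflets$central_bilayer)) stop("no central bilayer identified")
  topo <- topology
  box <- frame$box
  coms <- lipid_com(frame, topology)
  heads <- topo$species != "WATER" & topo$is_head
  hz <- frame$coords[heads, 3]
  hm <- topo$mass[heads]
  hlip <- topo$lipid_id[heads]
  head_rows <- split(seq_along(hz), hlip)
  midplane <- mean(leaflets$peak_z[leaflets$central_bilayer])
  gx <- (seq_len(G) - 0.5) * box[1] / G
  gy <- (seq_len(G) - 0.5) * box[2] / G
  vals <- matrix(NA_real_, G, G)
  valid <- matrix(FALSE, G, G)
  zr <- range(hz)
  breaks <- seq(zr[1] - bin, zr[2] + bin, by = bin)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  binidx <- findInterval(hz, breaks, rightmost.closed = TRUE)
  for (ix in seq_len(G)) {
    dx <- coms$x - gx[ix]
    dx <- dx - box[1] * round(dx / box[1])
    for (iy in seq_len(G)) {
      dy <- coms$y - gy[iy]
      dy <- dy - box[2] * round(dy / box[2])
      near <- which(dx * dx + dy * dy <= radius^2)
      if (length(near) < min_lipids) next
      rows <- unlist(head_rows[as.character(coms$lipid_id[near])],
                     use.names = FALSE)
      dens <- numeric(length(mids))
      tb <- rowsum(hm[rows], binidx[rows])
      dens[as.integer(rownames(tb))] <- tb
      pks <- flanking_peaks(mids, dens, midplane)
      if (is.null(pks)) next
      vals[ix, iy] <- pks[2] - pks[1]
      valid[ix, iy] <- TRUE
    }
  }
  new_gridmap(gx, gy, vals, valid, "thickness")
}

#' Local tail-composition map of the central bilayer
#'
#' At each grid point, the fraction of each of the four tail types
#' (CER acyl, CER sphingosine, CHOL, FFA — conformer-agnostic) among
#' central-bilayer tails whose center of mass lies within `radius`.
#' Fractions at a valid cell sum to 1.
#'
#' @inheritParams thickness_map
#' @param min_tails mask threshold (default 3 tails).
#' @return `sc_gridmap` with `values` a G x G x 4 array (dimnames give the
#'   tail type).
#' @export
composition_map <- function(frame, topology, leaflets, G = 50, radius = 0.8,
                            min_tails = 3) {
  tails <- central_bilayer_tails(frame, topology, leaflets)
  box <- frame$box
  gx <- (seq_len(G) - 0.5) * box[1] / G
  gy <- (seq_len(G) - 0.5) * box[2] / G
  vals <- array(NA_real_, c(G, G, 4), dimnames = list(NULL, NULL, TAIL_TYPES))
  valid <- matrix(FALSE, G, G)
  tfac <- factor(tails$tail_type, levels = TAIL_TYPES)
  for (ix in seq_len(G)) {
    dx <- tails$x - gx[ix]
    dx <- dx - box[1] * round(dx / box[1])
    for (iy in seq_len(G)) {
      dy <- tails$y - gy[iy]
      dy <- dy - box[2] * round(dy / box[2])
      near <- dx * dx + dy * dy <= radius^2
      n <- sum(near)
      if (n < min_tails) next
      vals[ix, iy, ] <- as.numeric(table(tfac[near])) / n
      valid[ix, iy] <- TRUE
    }
  }
  new_gridmap(gx, gy, vals, valid, "composition")
}

#' Pooled histogram of local bilayer thickness
#'
#' Pools valid cells of one or more thickness maps (frames, replicates)
#' into a fixed-bin histogram (default bin width 0.05 nm).
#'
#' @param maps a single `sc_gridmap` or list of them.
#' @param binwidth histogram bin width in nm.
#' @return data.frame `mid`, `count`, `density`.
#' @export
thickness_histogram <- function(maps, binwidth = 0.05) {
  if (inherits(maps, "sc_gridmap")) maps <- list(maps)
  v <- unlist(lapply(maps, function(m) m$values[m$valid]))
  if (!length(v)) stop("no valid cells to pool")
  pooled_histogram(v, binwidth)
}

#' Histograms of local excess/deficit tail fractions
#'
#' For each tail type, the deviation of the local fraction from the
#' pooled central-bilayer average fraction, over all valid cells of the
#' supplied composition maps (bin width 0.01). Positive values are local
#' excess, negative local deficit.
#'
#' @param maps a `sc_gridmap` of kind composition, or list of them.
#' @param binwidth histogram bin width (default 0.01).
#' @return named list of data.frames (`mid`, `count`, `density`), one per
#'   tail type; attribute `mean_fraction` holds the pooled averages.
#' @export
excess_fraction_histograms <- function(maps, binwidth = 0.01) {
  if (inherits(maps, "sc_gridmap")) maps <- list(maps)
  per_type <- lapply(TAIL_TYPES, function(tt)
    unlist(lapply(maps, function(m) m$values[, , tt][m$valid])))
  names(per_type) <- TAIL_TYPES
  if (!length(per_type[[1]])) stop("no valid cells to pool")
  mf <- vapply(per_type, mean, numeric(1))
  out <- lapply(TAIL_TYPES, function(tt)
    pooled_histogram(per_type[[tt]] - mf[tt], binwidth))
  names(out) <- TAIL_TYPES
  attr(out, "mean_fraction") <- mf
  out
}

pooled_histogram <- function(v, binwidth) {
  lo <- floor(min(v) / binwidth) * binwidth
  hi <- ceiling(max(v) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  breaks <- seq(lo - binwidth / 2, hi + binwidth / 2, by = binwidth)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts, density = h$density)
}

#' Write a grid map as CSV
#'
#' Thickness maps become one G x G matrix; composition maps one matrix per
#' tail type stacked with a `type` column.
#'
#' @param map an `sc_gridmap`.
#' @param path output path.
#' @export
write_gridmap_csv <- function(map, path) {
  if (map$kind == "thickness") {
    utils::write.csv(ifelse(map$valid, map$values, NA), path,
                     row.names = FALSE)
  } else {
    rows <- do.call(rbind, lapply(dimnames(map$values)[[3]], function(tt) {
      m <- ifelse(map$valid, map$values[, , tt], NA)
      df <- as.data.frame(m)
      df$type <- tt
      df
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' Render a grid map as a heatmap PNG
#'
#' @param map an `sc_gridmap` (thickness, or one type of a composition map
#'   via `type`).
#' @param path output PNG path.
#' @param type tail type for composition maps.
#' @export
plot_gridmap <- function(map, path, type = NULL) {
  v <- if (map$kind == "thickness") map$values else map$values[, , type]
  v[!map$valid] <- NA
  grDevices::png(path, width = 600, height = 560)
  on.exit(grDevices::dev.off())
  graphics::image(map$x, map$y, v, xlab = "x (nm)", ylab = "y (nm)",
                  main = if (is.null(type)) map$kind else type,
                  col = grDevices::hcl.colors(64, "viridis"), useRaster = TRUE)
  invisible(path)
}
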