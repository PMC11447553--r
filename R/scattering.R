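# Lamellar small-angle x-ray diffraction math: spacings and repeat
# distances from peak positions (d = 2 n pi / q_n), Pearson VII peak
# fitting, and greedy assignment of peaks to lamellar phases.

#' Spacing from a scattering-vector position
#'
#' `spacing = 2 pi / q`.
#'
#' @param q scattering vector, nm^-1 (> 0).
#' @return spacing in nm.
#' @export
spacing_from_q <- function(q) {
  if (any(q <= 0)) stop("q must be positive")
  2 * pi / q
}

#' Lamellar repeat distance from a diffraction order
#'
#' `d = 2 n pi / q_n` where n is the order number of the peak at q_n.
#'
#' @param q_n peak position, nm^-1 (> 0).
#' @param n diffraction order (>= 1).
#' @return repeat distance in nm.
#' @export
repeat_distance <- function(q_n, n) {
  if (any(q_n <= 0)) stop("q must be positive")
  if (any(n < 1)) stop("order must be >= 1")
  2 * n * pi / q_n
}

#' Pearson VII peak profile
#'
#' `A * [1 + ((q - q0)/w)^2 (2^(1/m) - 1)]^(-m)`: `w` is the half width at
#' half maximum and `m` the shape exponent, interpolating a Lorentzian
#' (m = 1) to a Gaussian (m -> infinity).
#'
#' @param q evaluation grid.
#' @param q0 peak center.
#' @param amplitude peak height.
#' @param width half width at half maximum (> 0).
#' @param shape exponent m (> 0.5).
#' @return intensities.
#' @export
pearson_vii <- function(q, q0, amplitude, width, shape) {
  if (width <= 0) stop("width must be positive")
  if (shape <= 0.5) stop("shape exponent must exceed 0.5")
  amplitude * (1 + ((q - q0) / width)^2 * (2^(1 / shape) - 1))^(-shape)
}

#' Fit Pearson VII peaks to a 1D scattering profile
#'
#' Levenberg-Marquardt least squares of a sum of Pearson VII peaks plus a
#' constant background. Initial values come from `init` (a data.frame of
#' starting `q0`, `amplitude`, `width`, `shape`); bounds keep w > 0 and
#' m > 0.5. Non-convergence is flagged, returning the last iterate.
#'
#' @param profile data.frame `q`, `intensity` (q strictly ascending).
#' @param init data.frame of starting peaks.
#' @param background fit a flat background term (default TRUE).
#' @param max_iter maximum iterations (default 500).
#' @return object of class `sc_peakfit`: `peaks` (fitted parameters),
#'   `background`, `converged`, `sse`, `fitted` curve.
#' @export
fit_pearson_vii <- function(profile, init, background = TRUE,
                            max_iter = 500) {
  stopifnot(all(c("q", "intensity") %in% names(profile)))
  if (is.unsorted(profile$q, strictly = TRUE)) stop("q must be ascending")
  np <- nrow(init)
  if (nrow(profile) < 5 * np)
    warning("fewer than 5 points per peak; fit may be unstable")
  model <- function(par, q) {
    I <- if (background) rep(par[4 * np + 1], length(q)) else numeric(length(q))
    for (i in seq_len(np)) {
      p <- par[(4 * (i - 1) + 1):(4 * i)]
      I <- I + pearson_vii(q, p[1], p[2], p[3], p[4])
    }
    I
  }
  start <- as.numeric(t(as.matrix(init[, c("q0", "amplitude", "width", "shape")])))
  if (background) start <- c(start, min(profile$intensity))
  lower <- rep(c(min(profile$q), 0, 1e-6, 0.51), np)
  upper <- rep(c(max(profile$q), Inf, Inf, Inf), np)
  if (background) { lower <- c(lower, -Inf); upper <- c(upper, Inf) }
  res <- minpack.lm::nls.lm(
    par = start,
    fn = function(par) profile$intensity - model(par, profile$q),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-12,
                                         ptol = 1e-12))
  par <- res$par
  peaks <- as.data.frame(matrix(par[seq_len(4 * np)], ncol = 4, byrow = TRUE))
  names(peaks) <- c("q0", "amplitude", "width", "shape")
  structure(list(peaks = peaks,
                 background = if (background) par[4 * np + 1] else 0,
                 converged = res$info %in% 1:4,
                 sse = sum(res$fvec^2),
                 fitted = model(par, profile$q),
                 q = profile$q),
            class = "sc_peakfit")
}

#' @export
print.sc_peakfit <- function(x, ...) {
  cat(sprintf("<sc_peakfit> %d peak(s), background %.4g, SSE %.4g%s\n",
              nrow(x$peaks), x$background, x$sse,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(x$peaks, 5), row.names = FALSE)
  invisible(x)
}

#' Assign diffraction peaks to lamellar phases
#'
#' Candidate repeat distances are generated from every peak at every order
#' 1..`max_order` and refined by least squares over their matching peaks.
#' A phase is reported when at least `min_orders` orders match within
#' `tol` and its first-order peak is itself observed (which suppresses
#' spurious doubled-repeat phases). Distinct phases may share overlapping
#' peaks, as lamellar series with commensurate repeats do. Peaks belonging
#' to no phase are reported as unknown-phase spacings `2 pi / q`.
#'
#' @param peaks_q observed peak positions, nm^-1.
#' @param tol matching tolerance in nm^-1 (default 0.02).
#' @param max_order highest diffraction order considered (default 4).
#' @param min_orders minimum matching orders per phase (default 2).
#' @return object of class `sc_lamellar`: `phases` data.frame
#'   (`d`, `n_orders`, `orders`, `peaks`), `unassigned` data.frame
#'   (`q`, `spacing`).
#' @export
assign_lamellar_phases <- function(peaks_q, tol = 0.02, max_order = 4,
                                   min_orders = 2) {
  if (!length(peaks_q)) stop("need at least one peak")
  peaks_q <- sort(peaks_q)
  cands <- list()
  for (q0 in peaks_q) for (n in seq_len(max_order)) {
    d <- repeat_distance(q0, n)
    # members: best order per peak, within tolerance
    nn <- pmax(1, pmin(max_order, round(peaks_q * d / (2 * pi))))
    resid <- peaks_q - 2 * pi * nn / d
    mem <- which(abs(resid) <= tol)
    if (length(mem) < min_orders) next
    # refine d on members, recheck membership
    beta <- sum(nn[mem] * peaks_q[mem]) / sum(nn[mem]^2)
    d <- 2 * pi / beta
    nn <- pmax(1, pmin(max_order, round(peaks_q * d / (2 * pi))))
    resid <- peaks_q - 2 * pi * nn / d
    mem <- which(abs(resid) <= tol)
    if (length(mem) < min_orders) next
    if (!any(nn[mem] == 1)) next      # first order must be observed
    if (anyDuplicated(nn[mem])) {     # keep best peak per order
      keep <- tapply(mem, nn[mem], function(ii) ii[which.min(abs(resid[ii]))])
      mem <- sort(as.integer(keep))
    }
    cands[[length(cands) + 1L]] <- list(d = d, members = mem,
                                        orders = nn[mem],
                                        sse = sum(resid[mem]^2))
  }
  phases <- list()
  if (length(cands)) {
    score <- vapply(cands, function(cn) c(length(cn$members), -cn$sse),
                    numeric(2))
    ord <- order(score[1, ], score[2, ], decreasing = TRUE)
    for (i in ord) {
      cn <- cands[[i]]
      if (length(phases) &&
          any(vapply(phases, function(p) abs(p$d - cn$d) <= 0.1, logical(1))))
        next  # near-duplicate repeat distance
      phases[[length(phases) + 1L]] <- cn
    }
  }
  assigned <- sort(unique(unlist(lapply(phases, function(p) p$members))))
  un <- setdiff(seq_along(peaks_q), assigned)
  phase_df <- if (length(phases)) data.frame(
    d = vapply(phases, function(p) p$d, numeric(1)),
    n_orders = vapply(phases, function(p) length(p$members), integer(1)),
    orders = vapply(phases, function(p) paste(p$orders, collapse = ","),
                    character(1)),
    peaks = vapply(phases, function(p)
      paste(sprintf("%.3f", peaks_q[p$members]), collapse = ","), character(1))
  ) else data.frame(d = numeric(0), n_orders = integer(0),
                    orders = character(0), peaks = character(0))
  structure(list(phases = phase_df[order(-phase_df$n_orders, phase_df$d), ],
                 unassigned = data.frame(q = peaks_q[un],
                                         spacing = if (length(un))
                                           spacing_from_q(peaks_q[un])
                                         else numeric(0))),
            class = "sc_lamellar")
}

#' @export
print.sc_lamellar <- function(x, ...) {
  cat("<sc_lamellar>\n")
  if (nrow(x$phases)) {
    p <- x$phases
    p$d <- round(p$d, 1)   # repeat distances reported at 0.1 nm precision
    cat("  lamellar phases:\n")
    print(p, row.names = FALSE)
  } else cat("  no lamellar phase (fewer than 2 matching orders)\n")
  if (nrow(x$unassigned)) {
    cat("  unknown-phase spacings (2 pi / q):\n")
    print(transform(x$unassigned, spacing = round(spacing, 1)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Read a two-column scattering profile
#'
#' @param path CSV/TSV with q (nm^-1) and intensity columns (header
#'   optional).
#' @return data.frame `q`, `intensity`.
#' @export
read_saxd_profile <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- !grepl("^[0-9eE+.,\t -]+$", first)
  df <- utils::read.table(path, header = has_header, sep = sep)
  df <- df[, 1:2]
  names(df) <- c("q", "intensity")
  if (is.unsorted(df$q, strictly = TRUE)) df <- df[order(df$q), ]
  if (any(df$q <= 0)) stop("q must be positive")
  df
}
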