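# Species / chain-role vocabularies used throughout. Head-bead names follow
# the coarse-grained convention: CER NS carries MHEAD2, AMIDE, OH1, OH2;
# FFA carries HEAD; CHOL carries CHEAD.
SPECIES_LEVELS <- c("CER_NS", "CHOL", "FFA", "WATER")
CHAIN_ROLES <- c("acyl", "sphingosine", "sterol", "fatty", "none")
TAIL_TYPES <- c("CER_acyl", "CER_sph", "CHOL", "FFA")
TAIL_CLASSES <- c("CER_acyl_ext", "CER_acyl_hp", "CER_sph_ext",
                  "CER_sph_hp", "CHOL", "FFA")
CER_HEAD_BEADS <- c("MHEAD2", "AMIDE", "OH1", "OH2")

#' Construct a particle topology table
#'
#' A topology maps every particle of a configuration to its lipid, species,
#' chain role, bead name, mass and head-vs-tail flag. Beads of one chain
#' must appear in head-proximal to chain-terminal order, so that the last
#' non-head bead of a chain is its terminal bead.
#'
#' @param df data.frame with columns `particle_index` (integer, >= 0),
#'   `lipid_id` (integer), `species` (one of CER_NS, CHOL, FFA, WATER),
#'   `chain_role` (acyl, sphingosine, sterol, fatty, none), `bead_name`,
#'   `mass` (amu, > 0) and `is_head` (logical).
#' @return the validated data.frame with class `sc_topology`.
#' @export
sc_topology <- function(df) {
  req <- c("particle_index", "lipid_id", "species", "chain_role",
           "bead_name", "mass", "is_head")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("topology is missing columns: ", paste(missing_cols, collapse = ", "))
  df$species <- as.character(df$species)
  df$chain_role <- as.character(df$chain_role)
  bad <- setdiff(unique(df$species), SPECIES_LEVELS)
  if (length(bad))
    stop("unknown species string(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$chain_role), CHAIN_ROLES)
  if (length(bad))
    stop("unknown chain_role string(s): ", paste(bad, collapse = ", "))
  if (any(df$mass <= 0)) stop("all bead masses must be positive")
  df$is_head <- as.logical(df$is_head)
  # every non-water lipid needs at least one head bead
  nw <- df[df$species != "WATER", ]
  if (nrow(nw)) {
    heads <- tapply(nw$is_head, nw$lipid_id, any)
    if (!all(heads))
      stop("lipid(s) without a head bead: ",
           paste(utils::head(names(heads)[!heads], 5), collapse = ", "))
  }
  class(df) <- c("sc_topology", "data.frame")
  df
}

#' Construct a single coordinate frame
#'
#' Coordinates are in nm with the bilayer normal along z. x-y coordinates
#' are treated as periodically wrapped; z is never re-wrapped (thickness
#' math requires monotone z).
#'
#' @param coords numeric n x 3 matrix of (x, y, z) positions in nm.
#' @param box numeric length-3 vector (Lx, Ly, Lz) in nm.
#' @param tag optional scalar tag (temperature in degC or time in ns).
#' @return list with class `sc_frame`.
#' @export
sc_frame <- function(coords, box, tag = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must have 3 columns")
  storage.mode(coords) <- "double"
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  structure(list(coords = coords, box = box, tag = tag), class = "sc_frame")
}

#' @export
print.sc_frame <- function(x, ...) {
  cat(sprintf("<sc_frame> %d particles, box %.2f x %.2f x %.2f nm%s\n",
              nrow(x$coords), x$box[1], x$box[2], x$box[3],
              if (!is.null(x$tag)) sprintf(", tag = %s", format(x$tag)) else ""))
  invisible(x)
}

#' Load a membrane system from a coordinate file plus topology table
#'
#' Accepts GRO (nm, possibly multi-frame) or PDB (Angstrom, possibly
#' multi-model) coordinates together with a sidecar topology CSV whose
#' header is exactly `particle_index,lipid_id,species,chain_role,bead_name,
#' mass,is_head`, or the package's native text container written by
#' [write_system()].
#'
#' @param coords_path path to a `.gro`, `.pdb` or `.scm` file. For `.scm`
#'   the topology is embedded and `topology_path` must be omitted.
#' @param topology_path path to the topology CSV.
#' @return list with elements `topology` (an `sc_topology`) and `frames`
#'   (list of `sc_frame`), classed `sc_system`.
#' @export
load_system <- function(coords_path, topology_path = NULL) {
  ext <- tolower(tools::file_ext(coords_path))
  if (ext == "scm") {
    if (!is.null(topology_path))
      stop("the native container embeds its topology; do not pass topology_path")
    return(read_system(coords_path))
  }
  if (is.null(topology_path)) stop("topology_path is required for GRO/PDB input")
  topo <- sc_topology(utils::read.csv(topology_path, stringsAsFactors = FALSE))
  frames <- switch(ext,
    gro = read_gro_frames(coords_path),
    pdb = read_pdb_frames(coords_path),
    stop("unsupported coordinate format: .", ext))
  for (fr in frames) {
    if (nrow(fr$coords) != nrow(topo))
      stop(sprintf("coordinate/topology particle count mismatch: %d vs %d",
                   nrow(topo), nrow(fr$coords)))
  }
  structure(list(topology = topo, frames = frames), class = "sc_system")
}

#' @export
print.sc_system <- function(x, ...) {
  cat(sprintf("<sc_system> %d particles, %d frame(s)\n",
              nrow(x$topology), length(x$frames)))
  invisible(x)
}

read_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop("malformed GRO file near line ", i + 1L)
    at <- lines[(i + 2L):(i + 1L + n)]
    x <- as.numeric(substr(at, 21, 28))
    y <- as.numeric(substr(at, 29, 36))
    z <- as.numeric(substr(at, 37, 44))
    box <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]])[1:3]
    frames[[length(frames) + 1L]] <- sc_frame(cbind(x, y, z), box)
    i <- i + 3L + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  # CRYST1 box (Angstrom) when present, otherwise coordinate extent
  cr <- grep("^CRYST1", readLines(path), value = TRUE)
  box_a <- if (length(cr)) as.numeric(c(substr(cr[1], 7, 15),
                                        substr(cr[1], 16, 24),
                                        substr(cr[1], 25, 33))) else NULL
  frames <- lapply(seq_len(nrow(xyz)), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE) / 10  # Angstrom -> nm
    box <- if (length(box_a) == 3 && all(is.finite(box_a)) && all(box_a > 0))
      box_a / 10 else apply(co, 2, function(v) diff(range(v))) + 1
    sc_frame(co, box)
  })
  frames
}

#' Write a system to GRO format
#'
#' Coordinates are written in nm at the format's fixed precision (0.001 nm);
#' one model per frame. Residue numbers are lipid ids (modulo the format's
#' five digits) and residue names abbreviate the species.
#'
#' @param system an `sc_system`.
#' @param path output path.
#' @export
write_gro <- function(system, path) {
  topo <- system$topology
  resname <- c(CER_NS = "CER", CHOL = "CHOL", FFA = "FFA", WATER = "W")[topo$species]
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in system$frames) {
    writeLines("multilayer configuration", con)
    writeLines(sprintf("%5d", nrow(topo)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       topo$lipid_id %% 100000L, resname,
                       substr(topo$bead_name, 1, 5),
                       (topo$particle_index + 1L) %% 100000L,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]), con)
  }
  invisible(path)
}

#' Write the native multi-frame text container
#'
#' Stores the topology once followed by per-frame coordinate blocks and box
#' vectors, as plain text with a version string (`SCLAMELLAR 1`).
#'
#' @param system an `sc_system`.
#' @param path output path (conventionally `.scm`).
#' @export
write_system <- function(system, path) {
  topo <- as.data.frame(system$topology)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("SCLAMELLAR 1", con)
  writeLines(sprintf("TOPOLOGY %d", nrow(topo)), con)
  writeLines(paste(topo$particle_index, topo$lipid_id, topo$species,
                   topo$chain_role, topo$bead_name,
                   format(topo$mass, digits = 10),
                   as.integer(topo$is_head)), con)
  for (fr in system$frames) {
    tag <- if (is.null(fr$tag)) "NA" else format(fr$tag, digits = 10)
    writeLines(sprintf("FRAME %d BOX %.6f %.6f %.6f TAG %s",
                       nrow(fr$coords), fr$box[1], fr$box[2], fr$box[3], tag), con)
    writeLines(sprintf("%.6f %.6f %.6f",
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Read the native multi-frame text container
#'
#' @param path path written by [write_system()].
#' @return an `sc_system`.
#' @export
read_system <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "SCLAMELLAR"))
    stop("not a sclamellar container (missing version string): ", path)
  ntop <- as.integer(sub("TOPOLOGY ", "", lines[2]))
  trows <- strsplit(lines[3:(2 + ntop)], " ", fixed = TRUE)
  tm <- do.call(rbind, trows)
  topo <- sc_topology(data.frame(
    particle_index = as.integer(tm[, 1]), lipid_id = as.integer(tm[, 2]),
    species = tm[, 3], chain_role = tm[, 4], bead_name = tm[, 5],
    mass = as.numeric(tm[, 6]), is_head = tm[, 7] == "1",
    stringsAsFactors = FALSE))
  frames <- list()
  i <- 3L + ntop
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    n <- as.integer(hdr[2])
    box <- as.numeric(hdr[4:6])
    tag <- if (hdr[8] == "NA") NULL else as.numeric(hdr[8])
    co <- do.call(rbind, strsplit(lines[(i + 1L):(i + n)], " ", fixed = TRUE))
    storage.mode(co) <- "double"
    frames[[length(frames) + 1L]] <- sc_frame(co, box, tag)
    i <- i + n + 1L
  }
  structure(list(topology = topo, frames = frames), class = "sc_system")
}

#' Minimum-image distance in the membrane plane
#'
#' Euclidean x-y distance under periodic boundary conditions. Vectorized
#' over rows of `a` and `b`.
#'
#' @param a,b numeric vectors (x, y) or matrices with x, y in the first two
#'   columns.
#' @param box in-plane box lengths (Lx, Ly).
#' @return numeric distances in nm.
#' @export
pbc_xy_distance <- function(a, b, box) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  if (any(box[1:2] <= 0)) stop("box lengths must be positive")
  dx <- a[, 1] - b[, 1]; dy <- a[, 2] - b[, 2]
  dx <- dx - box[1] * round(dx / box[1])
  dy <- dy - box[2] * round(dy / box[2])
  sqrt(dx * dx + dy * dy)
}

# local maxima of a numeric vector (plateaus collapse to their center)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) out <- c(out, as.integer(round((i + j) / 2)))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Assign lipids and tails to leaflets
#'
#' Leaflets are detected from a 1D histogram (bin 0.1 nm) of per-lipid
#' head-bead centroid z, smoothed with a 3-bin moving average; the
#' `n_leaflets` highest peaks define leaflet planes and every z is assigned
#' to the watershed basin of its nearest plane (basin boundaries at the
#' smoothed-density minimum between adjacent peaks). Leaflets are numbered
#' 1..K bottom to top; consecutive pairs (1,2), (3,4), ... form bilayers and
#' the central bilayer is the middle pair by mean z.
#'
#' @param frame an `sc_frame`.
#' @param topology an `sc_topology`.
#' @param n_leaflets even integer, default 6 (three-bilayer stack).
#' @param bin histogram bin width in nm.
#' @return object of class `sc_leaflets`: peak z positions (`peak_z`),
#'   basin `boundaries`, per-lipid assignment `lipid_leaflet` (named by
#'   lipid id), `pairs` matrix of bilayer leaflet pairs, `central_bilayer`.
#' @export
assign_leaflets <- function(frame, topology, n_leaflets = 6, bin = 0.1) {
  if (n_leaflets %% 2 != 0) stop("n_leaflets must be even")
  topo <- topology
  sel <- topo$species != "WATER" & topo$is_head
  if (!any(sel)) stop("no non-water head beads present")
  z <- frame$coords[sel, 3]
  headz <- tapply(z, topo$lipid_id[sel], mean)
  rng <- range(headz)
  breaks <- seq(rng[1] - bin, rng[2] + bin, by = bin)
  if (length(breaks) < 4)
    stop("leaflet detection failed: head-bead z range degenerate")
  h <- graphics::hist(headz, breaks = breaks, plot = FALSE)
  cnt <- as.numeric(stats::filter(h$counts, rep(1 / 3, 3), sides = 2))
  cnt[is.na(cnt)] <- h$counts[is.na(cnt)] / 3
  pk <- local_maxima(c(0, cnt, 0)) - 1L
  if (length(pk) < n_leaflets)
    stop(sprintf("leaflet detection failed: %d head-density band(s), need %d",
                 length(pk), n_leaflets))
  pk <- pk[order(cnt[pk], decreasing = TRUE)][seq_len(n_leaflets)]
  peak_z <- sort(h$mids[pk])
  # watershed boundary between adjacent peaks: center of the minimal
  # smoothed-density region between them
  bounds <- vapply(seq_len(n_leaflets - 1L), function(i) {
    lo <- which.min(abs(h$mids - peak_z[i]))
    hi <- which.min(abs(h$mids - peak_z[i + 1L]))
    seg <- cnt[lo:hi]
    mean(h$mids[lo:hi][seg == min(seg)])
  }, numeric(1))
  leaflet_of <- findInterval(headz, bounds) + 1L
  structure(list(peak_z = peak_z, boundaries = bounds,
                 lipid_leaflet = stats::setNames(leaflet_of, names(headz)),
                 pairs = matrix(seq_len(n_leaflets), ncol = 2, byrow = TRUE),
                 central_bilayer = {
                   nb <- n_leaflets / 2
                   ctr <- ceiling((nb + 1) / 2)
                   c(2L * ctr - 1L, 2L * ctr)
                 },
                 n_leaflets = as.integer(n_leaflets)),
            class = "sc_leaflets")
}

#' @export
print.sc_leaflets <- function(x, ...) {
  cat(sprintf("<sc_leaflets> %d leaflets at z = %s nm; central bilayer = (%d, %d)\n",
              x$n_leaflets, paste(sprintf("%.2f", x$peak_z), collapse = ", "),
              x$central_bilayer[1], x$central_bilayer[2]))
  invisible(x)
}

leaflet_of_z <- function(z, leaflets) findInterval(z, leaflets$boundaries) + 1L

#' Mass-weighted tail center of mass
#'
#' Center of mass of the non-head beads of one chain. No periodic
#' unwrapping is applied (chains never span the box in z and are stored
#' unwrapped in x-y).
#'
#' @param coords n x 3 matrix of the chain's non-head bead coordinates.
#' @param mass bead masses (amu).
#' @return numeric (x, y, z).
#' @export
tail_com <- function(coords, mass) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  if (length(mass) != nrow(coords)) stop("one mass per bead required")
  tot <- sum(mass)
  if (tot <= 0) stop("zero total mass")
  colSums(coords * mass) / tot
}

#' Enumerate lipid tail instances
#'
#' Builds one row per lipid chain: the acyl and sphingosine chains of each
#' CER NS (classified extended or hairpin), and the single chain of each
#' CHOL and FFA. Centers of mass use non-head beads only. The leaflet of a
#' CER tail is that of its terminal (chain-end) bead, so the two tails of
#' an extended CER land in adjacent leaflets; CHOL and FFA tails inherit
#' their lipid's head-centroid leaflet.
#'
#' @param frame an `sc_frame`.
#' @param topology an `sc_topology`.
#' @param leaflets an `sc_leaflets` from [assign_leaflets()].
#' @return data.frame: `lipid_id`, `tail_type` (CER_acyl, CER_sph, CHOL,
#'   FFA), `conformer` (extended/hairpin/not_applicable), `tail_class`
#'   (6-level key used by the neighbor analysis), `leaflet`, `x`, `y`, `z`.
#' @export
tail_instances <- function(frame, topology, leaflets) {
  topo <- topology
  tails <- topo[topo$species != "WATER" & !topo$is_head, ]
  co <- frame$coords[match(tails$particle_index, topo$particle_index), , drop = FALSE]
  key <- paste(tails$lipid_id, tails$chain_role)
  idx <- split(seq_len(nrow(tails)), key)
  rows <- lapply(idx, function(ii) {
    com <- tail_com(co[ii, , drop = FALSE], tails$mass[ii])
    term_z <- co[ii[length(ii)], 3]
    sp <- tails$species[ii[1]]
    data.frame(lipid_id = tails$lipid_id[ii[1]],
               tail_type = switch(tails$chain_role[ii[1]],
                                  acyl = "CER_acyl", sphingosine = "CER_sph",
                                  sterol = "CHOL", fatty = "FFA",
                                  stop("tail with chain_role 'none'")),
               species = sp, x = com[1], y = com[2], z = com[3],
               terminal_z = term_z, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  # leaflet: terminal-bead basin for CER tails, lipid head basin otherwise
  term_leaf <- leaflet_of_z(df$terminal_z, leaflets)
  lip_leaf <- leaflets$lipid_leaflet[as.character(df$lipid_id)]
  df$leaflet <- ifelse(df$species == "CER_NS", term_leaf, as.integer(lip_leaf))
  # conformer per CER lipid: extended iff the two tails sit in different leaflets
  df$conformer <- "not_applicable"
  cer <- df$species == "CER_NS"
  if (any(cer)) {
    leaf_by_lip <- split(df$leaflet[cer], df$lipid_id[cer])
    ext <- vapply(leaf_by_lip, function(l) {
      if (length(l) != 2) stop("CER lipid without both chains resolved")
      l[1] != l[2]
    }, logical(1))
    df$conformer[cer] <- ifelse(ext[as.character(df$lipid_id[cer])],
                                "extended", "hairpin")
  }
  df$tail_class <- tail_class_of(df$tail_type, df$conformer)
  df$species <- NULL
  df$terminal_z <- NULL
  df
}

tail_class_of <- function(tail_type, conformer) {
  ifelse(tail_type == "CER_acyl",
         ifelse(conformer == "extended", "CER_acyl_ext", "CER_acyl_hp"),
  ifelse(tail_type == "CER_sph",
         ifelse(conformer == "extended", "CER_sph_ext", "CER_sph_hp"),
         tail_type))
}

#' Classify a CER NS lipid as extended or hairpin
#'
#' A CER is extended when its acyl and sphingosine terminal beads lie in
#' different leaflets (one tail in the central bilayer, the other in the
#' adjacent leaflet of the neighboring bilayer) and hairpin when both tails
#' share a leaflet.
#'
#' @param lipid_id a CER NS lipid id present in the system.
#' @param frame,topology,leaflets as in [tail_instances()].
#' @return `"extended"` or `"hairpin"`.
#' @export
classify_cer_conformer <- function(lipid_id, frame, topology, leaflets) {
  topo <- topology
  sel <- topo$lipid_id == lipid_id & !topo$is_head & topo$species == "CER_NS"
  if (!any(sel)) stop("lipid ", lipid_id, " is not a CER NS lipid with resolved chains")
  sub <- topo[sel, ]
  co <- frame$coords[match(sub$particle_index, topo$particle_index), , drop = FALSE]
  roles <- split(seq_len(nrow(sub)), sub$chain_role)
  if (!all(c("acyl", "sphingosine") %in% names(roles)))
    stop("lipid ", lipid_id, " lacks one of its two chains")
  term_leaf <- vapply(roles, function(ii) {
    z <- co[ii[length(ii)], 3]
    lf <- leaflet_of_z(z, leaflets)
    if (lf < 1 || lf > leaflets$n_leaflets)
      stop("tail terminal bead unassignable to any leaflet")
    lf
  }, numeric(1))
  if (term_leaf[["acyl"]] != term_leaf[["sphingosine"]]) "extended" else "hairpin"
}

#' Whole-lipid centers of mass
#'
#' Mass-weighted center of mass over all beads of each non-water lipid.
#'
#' @inheritParams tail_instances
#' @return data.frame `lipid_id`, `x`, `y`, `z`.
#' @export
lipid_com <- function(frame, topology) {
  topo <- topology
  sel <- topo$species != "WATER"
  co <- frame$coords[sel, , drop = FALSE]
  m <- topo$mass[sel]
  id <- topo$lipid_id[sel]
  mx <- rowsum(co * m, id)
  mm <- rowsum(m, id)
  out <- data.frame(lipid_id = as.integer(rownames(mx)),
                    x = mx[, 1] / mm, y = mx[, 2] / mm, z = mx[, 3] / mm)
  rownames(out) <- NULL
  out
}
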