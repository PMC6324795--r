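# Synthetic morphology ------------------------------------------------------
#
# The reduced cell is a rooted tree of cylindrical compartments: one somatic
# compartment, an axon-initial-segment (AIS) chain, and unbranched dendrites.
# A compartment's `path_distance` is the distance (um) from the soma along the
# tree to the compartment midpoint; the soma itself sits at 0. Dendritic
# compartments below 300 um are "proximal" (stratum radiatum), the rest
# "distal" (stratum lacunosum-moleculare), mirroring the layer boundary used
# for layer-specific synaptic parameters.

PROXIMAL_BOUNDARY_UM <- 300

#' Build the default synthetic IS3-like morphology
#'
#' Generates a deterministic 221-compartment fixture: 1 somatic compartment,
#' an AIS chain, and `n_dendrites` unbranched dendrites of
#' `comps_per_dendrite` compartments each. The default geometry (17 dendrites
#' of 10 x 60 um compartments) puts exactly 85 dendritic compartments below
#' the 300 um proximal/distal boundary and 85 at or beyond it, which in turn
#' makes the full synapse bank split its excitatory capacity equally between
#' zones.
#'
#' @param n_dendrites Number of unbranched dendrites.
#' @param comps_per_dendrite Compartments per dendrite.
#' @param comp_length_um Dendritic compartment length (um).
#' @param dend_diam_um Dendritic diameter (um).
#' @param soma_length_um,soma_diam_um Somatic cylinder dimensions (um).
#' @param n_ais AIS compartments (chained from the soma).
#' @param ais_length_um,ais_diam_um AIS compartment dimensions (um).
#' @return A tibble of class `ivl_morphology` with one row per compartment:
#'   `id`, `parent_id` (`NA` for the somatic root), `length`, `diam`,
#'   `path_distance` (um, midpoint), and `region`
#'   (`"soma"`, `"AIS"`, `"dendrite"`).
#' @examples
#' m <- build_fixture_morphology()
#' nrow(m) # 221
#' @export
build_fixture_morphology <- function(n_dendrites = 17,
                                     comps_per_dendrite = 10,
                                     comp_length_um = 60,
                                     dend_diam_um = 0.5,
                                     soma_length_um = 10,
                                     soma_diam_um = 10,
                                     n_ais = 50,
                                     ais_length_um = 1,
                                     ais_diam_um = 1) {
  extent <- comps_per_dendrite * comp_length_um
  if (extent < PROXIMAL_BOUNDARY_UM) {
    abort(sprintf(
      "dendritic extent %g um cannot reach the %g um proximal/distal boundary",
      extent, PROXIMAL_BOUNDARY_UM
    ))
  }
  soma <- tibble::tibble(
    id = 1L, parent_id = NA_integer_, length = soma_length_um,
    diam = soma_diam_um, path_distance = 0, region = "soma"
  )
  ais <- tibble::tibble(
    id = 1L + seq_len(n_ais),
    parent_id = c(1L, head(1L + seq_len(n_ais), -1L)),
    length = ais_length_um, diam = ais_diam_um,
    path_distance = (seq_len(n_ais) - 0.5) * ais_length_um,
    region = "AIS"
  )
  dend <- purrr::map_dfr(seq_len(n_dendrites), function(j) {
    ids <- 1L + n_ais + (j - 1L) * comps_per_dendrite + seq_len(comps_per_dendrite)
    tibble::tibble(
      id = ids,
      parent_id = c(1L, head(ids, -1L)),
      length = comp_length_um, diam = dend_diam_um,
      path_distance = (seq_len(comps_per_dendrite) - 0.5) * comp_length_um,
      region = "dendrite"
    )
  })
  new_morphology(dplyr::bind_rows(soma, ais, dend))
}

new_morphology <- function(df) {
  df <- tibble::as_tibble(df)
  validate_morphology(df)
  class(df) <- c("ivl_morphology", class(df))
  df
}

validate_morphology <- function(df) {
  required <- c("id", "parent_id", "length", "diam", "path_distance", "region")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste("morphology is missing columns:", paste(missing, collapse = ", ")))
  }
  roots <- which(is.na(df$parent_id))
  if (length(roots) != 1L || df$region[roots] != "soma") {
    abort("morphology must have exactly one root compartment, the soma")
  }
  if (df$path_distance[roots] != 0) abort("somatic path_distance must be 0")
  idx <- match(df$parent_id, df$id)
  child <- which(!is.na(df$parent_id))
  if (anyNA(idx[child])) abort("parent_id refers to a missing compartment")
  if (any(idx[child] >= child)) {
    abort("compartments must be ordered parent-before-child (Hines order)")
  }
  bad <- df$path_distance[child] <= df$path_distance[idx[child]]
  if (any(bad)) abort("path_distance must strictly increase from parent to child")
  invisible(df)
}

#' Count dendritic compartments by proximal/distal zone
#'
#' @param morphology An `ivl_morphology`.
#' @return Tibble with `zone` and `n` for dendritic compartments, split at
#'   the 300 um path-distance boundary.
#' @export
zone_counts <- function(morphology) {
  tibble::as_tibble(morphology) |>
    dplyr::filter(.data$region == "dendrite") |>
    dplyr::mutate(zone = dendrite_zone(.data$path_distance)) |>
    dplyr::count(.data$zone)
}

dendrite_zone <- function(path_distance) {
  ifelse(path_distance < PROXIMAL_BOUNDARY_UM, "proximal", "distal")
}

#' A single-compartment (somatic) morphology
#'
#' One isopotential cylinder, useful as the analytic reference case for the
#' integrator (RC relaxation, exact input resistance, clamp recovery of
#' synaptic kernels without cable attenuation).
#'
#' @param length_um,diam_um Cylinder dimensions (um).
#' @return An `ivl_morphology` with one somatic compartment.
#' @export
single_compartment_morphology <- function(length_um = 10, diam_um = 10) {
  new_morphology(tibble::tibble(
    id = 1L, parent_id = NA_integer_, length = length_um, diam = diam_um,
    path_distance = 0, region = "soma"
  ))
}

# SWC serialization ----------------------------------------------------------
#
# Standard 7-column SWC: id, structure (1 soma, 2 axon/AIS, 3 dendrite),
# x, y, z, radius, parent (-1 for root). Each compartment is written as the
# point at its distal end; dendrites fan out at distinct azimuths in the xy
# plane and the AIS extends along -z, so segment lengths (and hence path
# distances) survive a write/read round trip to full double precision.

.swc_struct <- c(soma = 1L, AIS = 2L, dendrite = 3L)

#' Write a morphology to an SWC file
#'
#' @param morphology An `ivl_morphology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morphology, path) {
  df <- morphology
  n <- nrow(df)
  xyz <- matrix(0, n, 3)
  root <- which(is.na(df$parent_id))
  pidx <- match(df$parent_id, df$id)
  # direction per branch: AIS along -z, dendrite j at azimuth 2*pi*(j-1)/n_dend
  dend_first <- which(df$region == "dendrite" & !is.na(pidx) & pidx == root)
  n_dend <- length(dend_first)
  dirs <- matrix(0, n, 3)
  for (i in seq_len(n)[-root]) {
    p <- pidx[i]
    if (df$region[i] == "AIS") {
      dirs[i, ] <- c(0, 0, -1)
    } else if (p == root) {
      j <- match(i, dend_first)
      th <- 2 * pi * (j - 1) / max(n_dend, 1)
      dirs[i, ] <- c(cos(th), sin(th), 0)
    } else {
      dirs[i, ] <- dirs[p, ]
    }
    xyz[i, ] <- xyz[p, ] + dirs[i, ] * df$length[i]
  }
  lines <- sprintf(
    "%d %d %.17g %.17g %.17g %.17g %d",
    df$id, .swc_struct[df$region], xyz[, 1], xyz[, 2], xyz[, 3],
    df$diam / 2, ifelse(is.na(df$parent_id), -1L, df$parent_id)
  )
  writeLines(c("# SWC export (ivlsim synthetic morphology)", lines), path)
  invisible(path)
}

#' Read a morphology from an SWC file
#'
#' Rebuilds compartment lengths from inter-node distances and midpoint path
#' distances by accumulation from the somatic root. The somatic point's
#' length is taken as its diameter (single-point soma convention).
#'
#' @param path SWC file path.
#' @return An `ivl_morphology` tibble.
#' @export
read_swc <- function(path) {
  raw <- utils::read.table(path,
    comment.char = "#",
    col.names = c("id", "struct", "x", "y", "z", "radius", "parent")
  )
  raw <- raw[order(raw$id), ]
  region <- names(.swc_struct)[match(raw$struct, .swc_struct)]
  pidx <- match(raw$parent, raw$id)
  n <- nrow(raw)
  len <- numeric(n)
  path_end <- numeric(n) # cumulative cable distance at the node
  for (i in seq_len(n)) {
    if (is.na(pidx[i])) {
      len[i] <- 2 * raw$radius[i]
      path_end[i] <- 0
    } else {
      p <- pidx[i]
      len[i] <- sqrt(sum((unlist(raw[i, c("x", "y", "z")]) -
        unlist(raw[p, c("x", "y", "z")]))^2))
      path_end[i] <- path_end[p] + len[i]
    }
  }
  new_morphology(tibble::tibble(
    id = as.integer(raw$id),
    parent_id = ifelse(raw$parent < 0, NA_integer_, as.integer(raw$parent)),
    length = len,
    diam = 2 * raw$radius,
    path_distance = ifelse(is.na(pidx), 0, path_end - len / 2),
    region = region
  ))
}

#' @export
print.ivl_morphology <- function(x, ...) {
  counts <- table(x$region)
  cat(sprintf(
    "<ivl_morphology> %d compartments (%s)\n", nrow(x),
    paste(sprintf("%s: %d", names(counts), counts), collapse = ", ")
  ))
  NextMethod()
}
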