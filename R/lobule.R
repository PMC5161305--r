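#' Lobule geometry configuration
#'
#' Defines the fixed structural parameters of the three-zone lobule graph:
#' node counts per zone, the directed-edge partition, per-zone sinusoid
#' segment length ranges (grid spaces; lengths are drawn uniformly from
#' these ranges at each Monte Carlo build), the circumference range, and
#' the canonical hepatocyte census. The defaults encode the validated
#' lobule: 68 nodes (45/20/3 in zones 1-3), 99 edges partitioned as 55
#' zone-1-to-zone-2, 10 within zone 1, 24 zone-2-to-zone-3, 10 within
#' zone 2 and none within zone 3, and a census of 9310/3948/742
#' hepatocytes (14,000 per lobule). Mean segment lengths of 25/15/10 grid
#' spaces give a mean total path length `d_max = 50`.
#'
#' @param zone_nodes Integer vector of node counts for zones 1-3.
#' @param edge_counts Named list with elements `z1_z2`, `within_z1`,
#'   `z2_z3`, `within_z2`, `within_z3`.
#' @param length_range List of `c(lo, hi)` integer grid-space ranges per zone.
#' @param circumference_range `c(lo, hi)` integer range for segment
#'   circumference (grid spaces around the segment).
#' @param census Integer vector: hepatocytes per zone (fixed for every
#'   Monte Carlo variant; only dimensions and wiring vary).
#' @return An object of class `lobule_geometry`.
#' @export
lobule_geometry <- function(zone_nodes = c(45L, 20L, 3L),
                            edge_counts = list(z1_z2 = 55L, within_z1 = 10L,
                                               z2_z3 = 24L, within_z2 = 10L,
                                               within_z3 = 0L),
                            length_range = list(c(20L, 30L), c(12L, 18L),
                                                c(8L, 12L)),
                            circumference_range = c(6L, 10L),
                            census = c(9310L, 3948L, 742L)) {
  stopifnot(length(zone_nodes) == 3L, all(zone_nodes >= 1L),
            length(census) == 3L, all(census >= 0L),
            length(length_range) == 3L)
  for (r in length_range) {
    if (length(r) != 2L || r[1] < 1L || r[2] < r[1]) {
      stop("each length range must be c(lo, hi) with 1 <= lo <= hi",
           call. = FALSE)
    }
  }
  if (edge_counts$z1_z2 < max(zone_nodes[1], zone_nodes[2]) ||
      edge_counts$z2_z3 < max(zone_nodes[2], zone_nodes[3])) {
    stop("too few between-zone edges to place every segment on a flow path",
         call. = FALSE)
  }
  structure(list(zone_nodes = as.integer(zone_nodes),
                 edge_counts = lapply(edge_counts, as.integer),
                 length_range = lapply(length_range, as.integer),
                 circumference_range = as.integer(circumference_range),
                 census = as.integer(census)),
            class = "lobule_geometry")
}

# sample() without the scalar-x surprise (a length-1 range must yield
# that value, not sample from 1:x)
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Census-exact apportionment of zone hepatocytes over segments,
# proportional to segment length with round-robin remainder assignment.
apportion_census <- function(total, lengths) {
  if (length(lengths) == 0L) return(integer(0))
  base <- floor(total * lengths / sum(lengths))
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- rep_len(seq_along(lengths), rem)
    base <- base + tabulate(idx, nbins = length(lengths))
  }
  as.integer(base)
}

# Distinct random ordered pairs between two id sets, guaranteeing that every
# `from` id and every `to` id is covered at least once, n_edges total.
sample_bipartite_edges <- function(from_ids, to_ids, n_edges) {
  nf <- length(from_ids); nt <- length(to_ids)
  from_perm <- sample(from_ids)
  to_perm <- sample(to_ids)
  from <- from_perm
  to <- to_perm[((seq_len(nf) - 1L) %% nt) + 1L]
  extra <- n_edges - nf
  if (extra > 0) {
    all_pairs <- expand.grid(from = from_ids, to = to_ids)
    key <- paste(from, to)
    avail <- which(!(paste(all_pairs$from, all_pairs$to) %in% key))
    pick <- sample(avail, extra)
    from <- c(from, all_pairs$from[pick])
    to <- c(to, all_pairs$to[pick])
  }
  data.frame(from = as.integer(from), to = as.integer(to))
}

# Random within-zone edges that respect a random topological order (never a
# cycle back toward the periportal side).
sample_within_edges <- function(ids, n_edges) {
  if (n_edges == 0L) return(data.frame(from = integer(0), to = integer(0)))
  ord <- sample(ids)  # topological order
  pairs <- t(utils::combn(length(ord), 2L))
  pick <- sample(nrow(pairs), n_edges)
  data.frame(from = as.integer(ord[pairs[pick, 1L]]),
             to = as.integer(ord[pairs[pick, 2L]]))
}

#' Build a Monte Carlo lobule variant
#'
#' Constructs the three-zone directed graph of sinusoid segments. Segment
#' lengths and circumferences are drawn uniformly from the per-zone ranges;
#' edges are randomly assigned subject to the fixed edge partition, full
#' periportal-to-central-vein connectivity, and acyclicity (within-zone
#' edges follow a random topological order). The hepatocyte census is fixed:
#' zone totals always equal the canonical census, apportioned over segments
#' proportionally to length with round-robin remainders.
#'
#' The path-length offset of a zone-z segment is the sum over upstream zones
#' of that zone's mean drawn segment length, and `d_max` is the sum over all
#' three zones, so gradients are scaled by the lobule actually built.
#'
#' @param seed Integer seed (the same seed always reproduces the identical
#'   lobule). `NULL` uses the current RNG stream.
#' @param geometry A [lobule_geometry()].
#' @return An object of class `lobule` with elements `segments` (data frame:
#'   `id`, `zone`, `length`, `circumference`, `hepatocyte_count`,
#'   `dpp_offset`), `edges` (data frame `from`, `to`, `type`),
#'   `zone_node_counts`, `pp_entrance_ids`, `zone_mean_length`, `d_max`,
#'   `seed`, `geometry`.
#' @examples
#' lob <- build_lobule(seed = 1)
#' nrow(lob$segments)  # 68
#' nrow(lob$edges)     # 99
#' zone_census(lob)
#' @export
build_lobule <- function(seed = NULL, geometry = lobule_geometry()) {
  stopifnot(inherits(geometry, "lobule_geometry"))
  if (!is.null(seed)) set.seed(seed)
  zn <- geometry$zone_nodes
  ids <- list(seq_len(zn[1]),
              zn[1] + seq_len(zn[2]),
              zn[1] + zn[2] + seq_len(zn[3]))
  zone <- rep(1:3, zn)
  len <- integer(sum(zn)); circ <- integer(sum(zn))
  for (z in 1:3) {
    r <- geometry$length_range[[z]]
    len[ids[[z]]] <- resample(seq.int(r[1], r[2]), zn[z], replace = TRUE)
  }
  cr <- geometry$circumference_range
  circ[] <- resample(seq.int(cr[1], cr[2]), sum(zn), replace = TRUE)

  ec <- geometry$edge_counts
  e12 <- sample_bipartite_edges(ids[[1]], ids[[2]], ec$z1_z2)
  e11 <- sample_within_edges(ids[[1]], ec$within_z1)
  e23 <- sample_bipartite_edges(ids[[2]], ids[[3]], ec$z2_z3)
  e22 <- sample_within_edges(ids[[2]], ec$within_z2)
  e33 <- sample_within_edges(ids[[3]], ec$within_z3)
  parts <- list(z1_z2 = e12, within_z1 = e11, z2_z3 = e23,
                within_z2 = e22, within_z3 = e33)
  parts <- parts[vapply(parts, nrow, integer(1)) > 0L]
  edges <- do.call(rbind, lapply(names(parts), function(nm) {
    cbind(parts[[nm]], type = nm)
  }))
  rownames(edges) <- NULL

  hep <- integer(sum(zn))
  for (z in 1:3) {
    hep[ids[[z]]] <- apportion_census(geometry$census[z], len[ids[[z]]])
  }
  zone_means <- vapply(1:3, function(z) mean(len[ids[[z]]]), numeric(1))
  dpp_offset <- c(0, cumsum(zone_means))[zone]

  segments <- data.frame(id = seq_len(sum(zn)), zone = zone, length = len,
                         circumference = circ, hepatocyte_count = hep,
                         dpp_offset = dpp_offset)
  structure(list(segments = segments,
                 edges = edges,
                 zone_node_counts = stats::setNames(zn, 1:3),
                 pp_entrance_ids = ids[[1]],
                 zone_mean_length = zone_means,
                 d_max = sum(zone_means),
                 seed = seed,
                 geometry = geometry),
            class = "lobule")
}

#' @export
print.lobule <- function(x, ...) {
  cat(sprintf(
    "<lobule> %d sinusoid segments (%s per zone), %d edges, d_max = %.2f\n",
    nrow(x$segments), paste(x$zone_node_counts, collapse = "/"),
    nrow(x$edges), x$d_max))
  cat(sprintf("  hepatocyte census: %s (total %d)\n",
              paste(zone_census(x)$counts, collapse = "/"),
              sum(x$segments$hepatocyte_count)))
  invisible(x)
}

#' Hepatocyte positions of a lobule
#'
#' Enumerates every hepatocyte with its segment, axial grid position `x`
#' (0-based distance from the segment inlet; hepatocytes are spread
#' round-robin over columns, rings filling the circumference), zone, and
#' path-length coordinates.
#'
#' @param lobule A [build_lobule()] result.
#' @return Data frame with columns `cell`, `segment_id`, `x`, `ring_index`,
#'   `zone`, `dpp`, `dist_cv`.
#' @export
hepatocyte_positions <- function(lobule) {
  seg <- lobule$segments
  n <- seg$hepatocyte_count
  segment_id <- rep(seg$id, n)
  x <- unlist(lapply(seq_len(nrow(seg)), function(j) {
    if (n[j] == 0L) return(integer(0))
    (seq_len(n[j]) - 1L) %% seg$length[j]
  }), use.names = FALSE)
  ring <- unlist(lapply(seq_len(nrow(seg)), function(j) {
    if (n[j] == 0L) return(integer(0))
    (seq_len(n[j]) - 1L) %/% seg$length[j]
  }), use.names = FALSE)
  d <- x + seg$dpp_offset[segment_id]
  data.frame(cell = seq_along(segment_id), segment_id = segment_id,
             x = x, ring_index = ring, zone = seg$zone[segment_id],
             dpp = d, dist_cv = pmax(0, lobule$d_max - d))
}

#' Path length from the periportal entrance
#'
#' `dpp(h) = x + dpp_offset(segment)`, where the segment offset is the sum
#' over upstream zones of the zone-mean segment length.
#'
#' @param pos List or data frame with `segment_id` and `x`.
#' @param lobule A [build_lobule()] result.
#' @return Numeric vector of path lengths in grid spaces.
#' @export
dpp <- function(pos, lobule) {
  seg <- lobule$segments
  idx <- match(pos$segment_id, seg$id)
  if (anyNA(idx)) stop("unknown segment id", call. = FALSE)
  if (any(pos$x < 0 | pos$x >= seg$length[idx])) {
    stop("x must satisfy 0 <= x < segment length", call. = FALSE)
  }
  pos$x + seg$dpp_offset[idx]
}

#' Distance to the central vein
#'
#' `d_max - dpp`, floored at zero (positions deep in an unusually long
#' zone-3 segment can lie past the mean total path length).
#'
#' @inheritParams dpp
#' @return Numeric vector of distances in grid spaces.
#' @export
distance_to_cv <- function(pos, lobule) {
  pmax(0, lobule$d_max - dpp(pos, lobule))
}

#' Zone census of a lobule
#'
#' @param lobule A [build_lobule()] result.
#' @return A list of class `zone_census` with `counts` (named integer vector
#'   per zone) and `total`.
#' @export
zone_census <- function(lobule) {
  counts <- vapply(1:3, function(z) {
    sum(lobule$segments$hepatocyte_count[lobule$segments$zone == z])
  }, integer(1))
  structure(list(counts = stats::setNames(counts, 1:3),
                 total = sum(counts)), class = "zone_census")
}

#' @export
print.zone_census <- function(x, ...) {
  cat(sprintf("<zone_census> zone 1: %d, zone 2: %d, zone 3: %d (total %d)\n",
              x$counts[1], x$counts[2], x$counts[3], x$total))
  invisible(x)
}

# Deterministic reference lobule: every segment takes its zone's mean
# length (25/15/10) and circumference 8. Used for preset calibration, so
# the canonical dPP population does not depend on a Monte Carlo draw.
canonical_lobule <- function(geometry = lobule_geometry()) {
  means <- vapply(geometry$length_range, function(r) {
    as.integer(round(mean(r)))
  }, integer(1))
  geo <- geometry
  geo$length_range <- lapply(means, function(m) c(m, m))
  geo$circumference_range <- c(8L, 8L)
  build_lobule(seed = 1L, geometry = geo)
}

#' Canonical hepatocyte path-length population
#'
#' The `dPP` values of all hepatocytes of the deterministic reference lobule
#' (zone-mean segment lengths, canonical census). Mechanism presets use this
#' population to calibrate zonated gradients to whole-lobule mean targets.
#'
#' @param geometry A [lobule_geometry()].
#' @return List with `dpp` (numeric vector, one entry per hepatocyte),
#'   `d_max`, and `zone` (integer vector).
#' @export
canonical_dpp_population <- function(geometry = lobule_geometry()) {
  key <- paste(unlist(geometry$length_range), collapse = ",")
  cached <- .vlobule_cache$canonical[[key]]
  if (!is.null(cached)) return(cached)
  lob <- canonical_lobule(geometry)
  pos <- hepatocyte_positions(lob)
  out <- list(dpp = pos$dpp, d_max = lob$d_max, zone = pos$zone)
  .vlobule_cache$canonical[[key]] <- out
  out
}

.vlobule_cache <- new.env(parent = emptyenv())
.vlobule_cache$canonical <- list()
.vlobule_cache$presets <- list()

#' Export a lobule as node and edge tables
#'
#' Writes two RFC-4180 CSV files, `<stem>_segments.csv` (columns `id`,
#' `zone`, `length`, `circumference`, `hepatocyte_count`, `dpp_offset`) and
#' `<stem>_edges.csv` (`from`, `to`, `type`).
#'
#' @param lobule A [build_lobule()] result.
#' @param stem Output path stem.
#' @return Invisibly, the two file paths.
#' @export
export_lobule <- function(lobule, stem) {
  paths <- paste0(stem, c("_segments.csv", "_edges.csv"))
  utils::write.csv(lobule$segments, paths[1], row.names = FALSE)
  utils::write.csv(lobule$edges, paths[2], row.names = FALSE)
  invisible(paths)
}
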