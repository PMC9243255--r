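#' Generate a synthetic parcellation geometry
#'
#' Places `n_nodes` parcel centroids in 3D (millimetres) and assigns each a
#' network label by seeded k-means clustering of the coordinates, standing in
#' for a resting-state-network partition. Layouts: `"uniform_ball"` samples
#' uniformly inside a ball of given radius (default 70 mm, brain scale);
#' `"grid"` places nodes on a cubic lattice with the given spacing;
#' `"from_file"` reads a TSV with columns `node_id, x, y, z`.
#'
#' @param n_nodes number of parcels (>= 2); ignored for `from_file`.
#' @param layout one of `"uniform_ball"`, `"grid"`, `"from_file"`.
#' @param n_networks number of network labels to assign.
#' @param seed integer seed; the result is a pure function of the arguments.
#' @param radius ball radius in mm for `uniform_ball`.
#' @param spacing lattice spacing in mm for `grid`.
#' @param file path to a coordinate TSV for `from_file`.
#' @return An object of class `"parcellation"`: list with `node_ids`
#'   (character), `coords` (n x 3 matrix, mm) and `network` (factor).
#' @export
generate_parcellation <- function(n_nodes = 100,
                                  layout = c("uniform_ball", "grid", "from_file"),
                                  n_networks = 8, seed = 1,
                                  radius = 70, spacing = 10, file = NULL) {
  layout <- match.arg(layout)
  if (layout == "from_file") {
    coords <- read_coordinates(file)
    node_ids <- rownames(coords)
    n_nodes <- nrow(coords)
  } else {
    stopifnot(n_nodes >= 2)
    if (layout == "uniform_ball") {
      set.seed(derive_seed(seed, tag = "geom"))
      coords <- matrix(NA_real_, 0, 3)
      while (nrow(coords) < n_nodes) {
        cand <- matrix(runif(3 * 2 * n_nodes, -radius, radius), ncol = 3)
        cand <- cand[rowSums(cand^2) <= radius^2, , drop = FALSE]
        coords <- rbind(coords, cand)
      }
      coords <- coords[seq_len(n_nodes), , drop = FALSE]
    } else {
      side <- ceiling(n_nodes^(1 / 3))
      g <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                 z = seq_len(side)))
      coords <- (g[seq_len(n_nodes), , drop = FALSE] - 1) * spacing
    }
    node_ids <- sprintf("n%03d", seq_len(n_nodes))
    rownames(coords) <- node_ids
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates in geometry")
  colnames(coords) <- c("x", "y", "z")

  n_networks <- min(n_networks, n_nodes)
  if (n_networks >= n_nodes) {
    lab <- seq_len(n_nodes)
  } else {
    set.seed(derive_seed(seed, tag = "networks"))
    km <- kmeans(coords, centers = n_networks, nstart = 5)
    # relabel clusters in order of first appearance so labels are stable
    first <- order(match(seq_len(n_networks), km$cluster))
    lab <- match(km$cluster, first)
  }
  network <- factor(paste0("net", lab), levels = paste0("net", seq_len(n_networks)))

  structure(list(node_ids = node_ids, coords = coords, network = network),
            class = "parcellation")
}

#' Read node coordinates from a TSV file
#'
#' Expects 4 tab-separated columns per row: node_id, x, y, z (header optional).
#' Malformed rows raise an error naming the offending line.
#'
#' @param file path to the TSV.
#' @return numeric matrix with one row per node, rownames = node ids.
#' @export
read_coordinates <- function(file) {
  if (is.null(file) || !file.exists(file)) {
    stop("coordinate file not found: ", file)
  }
  lines <- readLines(file)
  start <- 1L
  if (length(lines) && grepl("^\\s*node_id\\b", lines[1])) start <- 2L
  rows <- lapply(seq(start, length(lines)), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4 || anyNA(suppressWarnings(as.numeric(f[2:4])))) {
      stop("malformed coordinate row at line ", i, ": '", lines[i], "'")
    }
    f
  })
  ids <- vapply(rows, `[`, "", 1)
  if (anyDuplicated(ids)) stop("duplicate node ids in ", file)
  coords <- do.call(rbind, lapply(rows, function(f) as.numeric(f[2:4])))
  rownames(coords) <- ids
  colnames(coords) <- c("x", "y", "z")
  coords
}

#' Write a parcellation's coordinates to TSV
#'
#' @param geom a `"parcellation"` object.
#' @param file output path.
#' @export
write_coordinates <- function(geom, file) {
  df <- data.frame(node_id = geom$node_ids, geom$coords,
                   check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Pairwise Euclidean distances between parcels
#'
#' @param geom a `"parcellation"` object (or an n x 3 coordinate matrix).
#' @return symmetric node x node matrix of distances in mm, zero diagonal.
#' @export
pairwise_distances <- function(geom) {
  coords <- if (inherits(geom, "parcellation")) geom$coords else geom
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- list(rownames(coords), rownames(coords))
  d
}

#' Build a structural connectome from the exponential distance rule
#'
#' Connection weights decay exponentially with Euclidean distance,
#' `C[n,p] = exp(-lambda_c * r(n,p))`, the exponential distance rule (EDR).
#' Optional long-range entries (standing in for tractography-derived
#' connections) are added on top and symmetrised.
#'
#' @param dist node x node distance matrix in mm.
#' @param lambda_c EDR decay constant in 1/mm (> 0); default 0.18, a
#'   literature-typical structural decay scale.
#' @param long_range optional data.frame with columns `from`, `to`, `weight`
#'   (node indices or ids) of additive long-range connections.
#' @param keep_diagonal logical; the diagonal is zeroed by default and the
#'   choice is recorded on the object.
#' @return An object of class `"connectome"`: list with `weights` (matrix),
#'   `lambda_c`, `provenance` and `zero_diagonal`.
#' @export
build_connectome <- function(dist, lambda_c = 0.18, long_range = NULL,
                             keep_diagonal = FALSE) {
  stopifnot(lambda_c > 0, is.matrix(dist), nrow(dist) == ncol(dist))
  w <- exp(-lambda_c * dist)
  if (!keep_diagonal) diag(w) <- 0
  provenance <- "edr"
  if (!is.null(long_range) && nrow(long_range) > 0) {
    idx <- function(v) {
      if (is.character(v) || is.factor(v)) {
        i <- match(as.character(v), rownames(dist))
      } else i <- as.integer(v)
      if (anyNA(i) || any(i < 1) || any(i > nrow(dist))) {
        stop("long_range entry references unknown node")
      }
      i
    }
    i <- idx(long_range$from); j <- idx(long_range$to)
    for (k in seq_along(i)) {
      w[i[k], j[k]] <- w[i[k], j[k]] + long_range$weight[k]
      w[j[k], i[k]] <- w[j[k], i[k]] + long_range$weight[k]
    }
    provenance <- "edr_plus_long_range"
  }
  structure(list(weights = w, lambda_c = lambda_c, provenance = provenance,
                 zero_diagonal = !keep_diagonal),
            class = "connectome")
}
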