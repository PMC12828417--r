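#' Train an emergent self-organizing map on a dataset
#'
#' Projects the z-standardized feature table onto a large rectangular neuron
#' lattice with the classical online update rule: for each presented sample
#' the best matching unit (BMU) is found and every neuron is pulled towards
#' the sample proportionally to a Gaussian neighborhood kernel around the
#' BMU, with learning rate and neighborhood radius decaying linearly over
#' epochs. "Emergent" refers to the use of many more neurons than data
#' points, so that cluster structure emerges in the collective layout of
#' the prototypes rather than in single neurons.
#'
#' Training is deterministic for a fixed seed: initial weights and the
#' per-epoch presentation orders are drawn up front from the seed and the
#' numerical loop itself is deterministic. BMU ties break to the lowest
#' neuron index.
#'
#' @param data a [tabular_dataset]; features are z-standardized internally
#'   (per-column mean 0, sd 1) before training.
#' @param rows,cols lattice dimensions; defaults 50 x 80 follow the
#'   emergent-SOM convention of several thousand neurons.
#' @param epochs number of passes over the data (default 24).
#' @param seed integer seed controlling weight initialization and
#'   presentation order.
#' @param topology `"toroidal"` (default; lattice distances wrap around,
#'   avoiding border effects) or `"planar"`.
#' @param lr learning-rate range, decayed linearly from `lr[1]` to `lr[2]`.
#' @param radius neighborhood-radius range on the lattice, decayed linearly;
#'   defaults from half the smaller lattice dimension down to 1. This SOM
#'   neighborhood radius is unrelated to the critical generative radius
#'   estimated by [critical_radius()].
#'
#' @return An object of class `esom_grid`: list with `weights` (m x J
#'   prototype matrix), `bmu` (1-based neuron index per data row), `rows`,
#'   `cols`, `topology`, `center`/`scale` (the standardization applied),
#'   `schedule`, and lattice coordinates `grid_row`/`grid_col`.
#' @export
#' @examples
#' d <- make_ascending_significance(n_v = 5, n_per_class = 10, seed = 1)
#' g <- train_esom(d, rows = 8, cols = 10, epochs = 5, seed = 1)
#' table(g$bmu)
train_esom <- function(data, rows = 50, cols = 80, epochs = 24, seed = 42,
                       topology = c("toroidal", "planar"),
                       lr = c(0.5, 0.1), radius = NULL) {
  validate_dataset(data)
  topology <- match.arg(topology)
  if (rows * cols < 4) stop("lattice must have at least 4 neurons")
  if (epochs < 1) stop("epochs must be >= 1")
  n <- nrow(data$values)
  m <- as.integer(rows * cols)

  std <- standardize_values(data$values)
  X <- std$z

  if (is.null(radius)) radius <- c(min(rows, cols) / 2, 1)
  etas <- seq(lr[1], lr[2], length.out = epochs)
  radii <- seq(radius[1], radius[2], length.out = epochs)
  radii <- pmax(radii, 1e-8)

  # lattice coordinates, row-major, 0-based
  grid_row <- rep(0:(rows - 1), each = cols)
  grid_col <- rep(0:(cols - 1), times = rows)

  init <- with_seed(seed, {
    lo <- apply(X, 2, min)
    hi <- apply(X, 2, max)
    W0 <- matrix(stats::runif(m * ncol(X)), m, ncol(X))
    W0 <- sweep(sweep(W0, 2, hi - lo, "*"), 2, lo, "+")
    orders <- t(vapply(seq_len(epochs),
                       function(e) sample.int(n) - 1L, integer(n)))
    list(W0 = W0, orders = orders)
  })

  fit <- esom_train_cpp(X, init$W0, as.integer(grid_row), as.integer(grid_col),
                        init$orders, etas, radii,
                        as.integer(rows), as.integer(cols),
                        topology == "toroidal")
  W <- fit$weights
  colnames(W) <- colnames(data$values)

  structure(
    list(weights = W, bmu = fit$bmu,
         rows = as.integer(rows), cols = as.integer(cols),
         topology = topology,
         grid_row = grid_row, grid_col = grid_col,
         center = std$center, scale = std$scale,
         schedule = list(epochs = epochs, eta = etas, radius = radii),
         seed = seed),
    class = "esom_grid")
}

#' Construct an ESOM grid from explicit weights
#'
#' Low-level constructor, mainly for building toy lattices in examples and
#' for importing externally trained maps. Weights are taken as-is (assumed
#' to live in the same space as the data they will be compared with).
#'
#' @param weights m x J prototype matrix, neurons in row-major lattice order.
#' @param rows,cols lattice dimensions with `rows * cols == nrow(weights)`.
#' @param topology `"toroidal"` or `"planar"`.
#' @param bmu optional 1-based BMU assignment per data row.
#' @param center,scale optional standardization parameters carried along.
#' @return an `esom_grid` object.
#' @export
new_esom_grid <- function(weights, rows, cols,
                          topology = c("toroidal", "planar"),
                          bmu = NULL, center = NULL, scale = NULL) {
  topology <- match.arg(topology)
  weights <- as.matrix(weights)
  if (nrow(weights) != rows * cols) {
    stop("nrow(weights) must equal rows * cols")
  }
  if (is.null(center)) center <- rep(0, ncol(weights))
  if (is.null(scale)) scale <- rep(1, ncol(weights))
  structure(
    list(weights = weights, bmu = bmu,
         rows = as.integer(rows), cols = as.integer(cols),
         topology = topology,
         grid_row = rep(0:(rows - 1), each = cols),
         grid_col = rep(0:(cols - 1), times = rows),
         center = center, scale = scale,
         schedule = NULL, seed = NA_integer_),
    class = "esom_grid")
}

#' @export
print.esom_grid <- function(x, ...) {
  cat(sprintf("esom_grid: %d x %d %s lattice (%d neurons, %d features)\n",
              x$rows, x$cols, x$topology, nrow(x$weights), ncol(x$weights)))
  if (!is.null(x$bmu)) {
    cat(sprintf("occupied neurons: %d of %d\n",
                length(unique(x$bmu)), nrow(x$weights)))
  }
  invisible(x)
}

# 1-based neuron indices of the lattice neighbors of neuron i
# (8-neighborhood; wraps when toroidal, drops off-lattice when planar)
lattice_neighbors <- function(grid, i) {
  r <- grid$grid_row[i]
  c <- grid$grid_col[i]
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  nr <- r + off$dr
  nc <- c + off$dc
  if (grid$topology == "toroidal") {
    nr <- nr %% grid$rows
    nc <- nc %% grid$cols
  } else {
    ok <- nr >= 0 & nr < grid$rows & nc >= 0 & nc < grid$cols
    nr <- nr[ok]
    nc <- nc[ok]
  }
  unique(nr * grid$cols + nc + 1L)
}

#' Compute the U-matrix of a trained grid
#'
#' The U-matrix assigns to each neuron the mean Euclidean distance between
#' its weight vector and the weight vectors of its lattice neighbors
#' (8-neighborhood; wrapping on toroidal lattices). High values form ridges
#' that mark cluster boundaries in the data.
#'
#' @param grid an `esom_grid`.
#' @return numeric vector of per-neuron heights (all `>= 0`), in row-major
#'   lattice order.
#' @export
compute_umatrix <- function(grid) {
  stopifnot(inherits(grid, "esom_grid"))
  W <- grid$weights
  if (is.null(W) || !all(is.finite(W))) stop("grid has no finite trained weights")
  m <- nrow(W)
  heights <- numeric(m)
  for (i in seq_len(m)) {
    nb <- lattice_neighbors(grid, i)
    diffs <- sweep(W[nb, , drop = FALSE], 2, W[i, ], "-")
    heights[i] <- mean(sqrt(rowSums(diffs^2)))
  }
  heights
}

#' Compute the P-matrix (empirical density) of a trained grid
#'
#' For each neuron, counts the data points lying within a hypersphere of
#' the given radius around its prototype vector. Data are mapped into the
#' grid's standardized space before distances are taken, so the radius is
#' expressed in the same (z-score) units as the critical radius.
#'
#' @param grid an `esom_grid`.
#' @param data a [tabular_dataset] with the same feature columns the grid
#'   was trained on.
#' @param radius hypersphere radius (`> 0`), in standardized units.
#' @return integer vector of per-neuron counts in `[0, n]`.
#' @export
compute_pmatrix <- function(grid, data, radius) {
  stopifnot(inherits(grid, "esom_grid"))
  if (length(radius) != 1 || !is.finite(radius) || radius <= 0) {
    stop("radius must be a single positive number")
  }
  X <- standardize_values(data$values, grid$center, grid$scale)$z
  W <- grid$weights
  if (nrow(X) == 0) return(integer(nrow(W)))
  # squared distances neuron x data via the expansion |w|^2 + |x|^2 - 2 w.x
  d2 <- outer(rowSums(W^2), rowSums(X^2), "+") - 2 * W %*% t(X)
  d2[d2 < 0] <- 0
  as.integer(rowSums(d2 <= radius^2 + 1e-12))
}

#' Export a trained grid as a plain-text table
#'
#' Writes one row per neuron with its lattice position and weight vector,
#' for inspection outside R.
#'
#' @param grid an `esom_grid`.
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
export_grid <- function(grid, path, sep = ",") {
  df <- data.frame(row = grid$grid_row, col = grid$grid_col,
                   grid$weights, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
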