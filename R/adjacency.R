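#' County adjacency structure in flattened neighbor-list form
#'
#' The representation used by the field's spatial model files: `adj` is the
#' concatenation of each county's neighbor indices, `num` gives the neighbor
#' count per county, `weights` are unit edge weights, and
#' `sumNumNeigh = length(adj) = sum(num)`.
#'
#' @param neighbors list of integer vectors; `neighbors[[j]]` holds the
#'   indices of county j's neighbors.
#' @param county_ids optional labels (default `1:M` as character).
#' @return an object of class `adjacency_structure` with elements `adj`,
#'   `num`, `weights`, `sumNumNeigh`, `county_ids`, `n`, `neighbors`.
#' @export
adjacency_structure <- function(neighbors, county_ids = NULL) {
  n <- length(neighbors)
  neighbors <- lapply(neighbors, function(v) sort(as.integer(v)))
  for (j in seq_len(n)) {
    nb <- neighbors[[j]]
    if (any(nb == j)) stop("self-neighbor at county ", j)
    if (any(nb < 1L) || any(nb > n)) stop("neighbor index out of range at ", j)
    for (i in nb) {
      if (!(j %in% neighbors[[i]])) {
        stop("asymmetric adjacency: ", j, " lists ", i, " but not vice versa")
      }
    }
  }
  num <- lengths(neighbors)
  adj <- unlist(neighbors, use.names = FALSE)
  if (is.null(adj)) adj <- integer(0)
  structure(list(adj = adj, num = as.integer(num),
                 weights = rep(1, length(adj)),
                 sumNumNeigh = length(adj),
                 county_ids = county_ids %||% as.character(seq_len(n)),
                 n = n, neighbors = neighbors),
            class = "adjacency_structure")
}

#' @export
print.adjacency_structure <- function(x, ...) {
  cat("Adjacency structure:", x$n, "counties,", x$sumNumNeigh / 2,
      "edges (sumNumNeigh =", x$sumNumNeigh, ")\n")
  invisible(x)
}

# connected components by breadth-first search; returns membership vector
connected_components <- function(adjacency) {
  n <- adjacency$n
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adjacency$neighbors[[v]]) {
        if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

#' Test whether an adjacency structure is connected
#' @param adjacency an [adjacency_structure].
#' @return logical.
#' @export
is_connected <- function(adjacency) {
  adjacency$n <= 1L || max(connected_components(adjacency)) == 1L
}

# unordered neighbor pairs (i < j), one row per edge
edge_list <- function(adjacency) {
  i <- rep(seq_len(adjacency$n), adjacency$num)
  j <- adjacency$adj
  keep <- i < j
  cbind(i = i[keep], j = j[keep])
}

#' Generate a county adjacency graph
#'
#' Two generators: `"lattice"` builds a near-square grid (rook neighbors),
#' dropping trailing cells row-major when `n_counties` is not a full
#' rectangle, which keeps the graph connected; `"random-planar"` draws
#' uniform points in the unit square and connects them by the Gabriel graph,
#' which is planar and always connected, resembling an irregular county map.
#'
#' @param n_counties number of counties (>= 2).
#' @param kind `"lattice"` or `"random-planar"`.
#' @param seed integer seed (used by `"random-planar"`).
#' @param max_attempts retry bound for a disconnected random draw.
#' @return an [adjacency_structure]: symmetric, self-loop-free, connected.
#' @examples
#' a <- generate_adjacency(4, "lattice")
#' a$num  # each corner of the 2x2 grid has 2 neighbors
#' @export
generate_adjacency <- function(n_counties, kind = c("lattice", "random-planar"),
                               seed = 1L, max_attempts = 50L) {
  if (n_counties < 2L) stop("n_counties must be at least 2")
  kind <- match.arg(kind)
  if (kind == "lattice") {
    nr <- floor(sqrt(n_counties))
    nc <- ceiling(n_counties / nr)
    cell <- function(r, c) (r - 1L) * nc + c  # row-major id, NA if dropped
    neighbors <- vector("list", n_counties)
    for (id in seq_len(n_counties)) {
      r <- (id - 1L) %/% nc + 1L
      c <- (id - 1L) %% nc + 1L
      nb <- c(if (r > 1L) cell(r - 1L, c),
              if (c > 1L) cell(r, c - 1L),
              cell(r + 1L, c), cell(r, c + 1L))
      nb <- nb[!is.na(nb) & nb <= n_counties &
                 # right neighbor only when not wrapping past the row end
                 !(c == nc & nb == id + 1L)]
      neighbors[[id]] <- nb
    }
    return(adjacency_structure(neighbors))
  }
  # random-planar: Gabriel graph of uniform points (contains the Euclidean
  # MST, hence connected; retry loop kept as a guard for degenerate draws)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    pts <- cbind(stats::runif(n_counties), stats::runif(n_counties))
    neighbors <- gabriel_neighbors(pts)
    a <- adjacency_structure(neighbors)
    if (is_connected(a)) return(a)
  }
  comp <- connected_components(a)
  stop("could not draw a connected adjacency in ", max_attempts,
       " attempts; last draw had components ",
       paste(tabulate(comp), collapse = ", "))
}

gabriel_neighbors <- function(pts) {
  n <- nrow(pts)
  d2 <- as.matrix(stats::dist(pts))^2
  neighbors <- lapply(seq_len(n), function(i) integer(0))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      mid <- (pts[i, ] + pts[j, ]) / 2
      r2 <- d2[i, j] / 4
      dmid <- (pts[, 1] - mid[1])^2 + (pts[, 2] - mid[2])^2
      # Gabriel: no third point strictly inside the circle on diameter ij
      if (all(dmid[-c(i, j)] >= r2 - 1e-12)) {
        neighbors[[i]] <- c(neighbors[[i]], j)
        neighbors[[j]] <- c(neighbors[[j]], i)
      }
    }
  }
  neighbors
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write an adjacency structure as JSON
#'
#' Keys: `adj` (flattened neighbor list), `num` (per-county neighbor counts),
#' `sumNumNeigh`, `county_ids`.
#' @param adjacency an [adjacency_structure].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_adjacency_json <- function(adjacency, path) {
  jsonlite::write_json(
    list(adj = adjacency$adj, num = adjacency$num,
         sumNumNeigh = adjacency$sumNumNeigh,
         county_ids = adjacency$county_ids),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Read an adjacency structure from JSON written by [write_adjacency_json()]
#' @param path JSON path.
#' @return an [adjacency_structure].
#' @export
read_adjacency_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ends <- cumsum(obj$num)
  starts <- ends - obj$num + 1L
  neighbors <- lapply(seq_along(obj$num), function(j) {
    if (obj$num[j] == 0L) integer(0) else obj$adj[starts[j]:ends[j]]
  })
  adjacency_structure(neighbors, county_ids = obj$county_ids)
}

#' Sample intrinsic-CAR county effects on the sum-to-zero subspace
#'
#' The intrinsic CAR prior with precision `tau_c` is improper (flat along the
#' constant vector); draws are made proper by restricting to the sum-to-zero
#' subspace via the eigen-decomposition of the graph Laplacian `L = D - W`:
#' phi = sum over positive eigenvalues of `v_i z_i / sqrt(tau_c lambda_i)`,
#' then centered exactly.
#'
#' @param adjacency a connected [adjacency_structure].
#' @param tau_c CAR precision (> 0).
#' @param n_draws number of draws.
#' @return a vector (one draw) or `n_draws` x M matrix; each draw has mean
#'   exactly zero.
#' @export
sample_car_effects <- function(adjacency, tau_c, n_draws = 1L) {
  if (tau_c <= 0) stop("tau_c must be > 0")
  if (!is_connected(adjacency)) {
    comp <- connected_components(adjacency)
    stop("adjacency is disconnected (components of sizes ",
         paste(tabulate(comp), collapse = ", "), ")")
  }
  L <- laplacian_matrix(adjacency)
  eg <- eigen(L, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  V <- eg$vectors[, pos, drop = FALSE]
  lam <- eg$values[pos]
  z <- matrix(stats::rnorm(n_draws * length(lam)), nrow = length(lam))
  draws <- t(V %*% (z / sqrt(tau_c * lam)))
  draws <- draws - rowMeans(draws)
  if (n_draws == 1L) drop(draws) else draws
}

#' Graph Laplacian of an adjacency structure
#'
#' `L = D - W` with unit edge weights; the quadratic form `phi' L phi` equals
#' the pairwise CAR sum over unordered neighbor pairs.
#' @param adjacency an [adjacency_structure].
#' @return an M x M symmetric matrix.
#' @export
laplacian_matrix <- function(adjacency) {
  n <- adjacency$n
  L <- matrix(0, n, n)
  e <- edge_list(adjacency)
  for (k in seq_len(nrow(e))) {
    i <- e[k, 1L]; j <- e[k, 2L]
    L[i, j] <- L[i, j] - 1
    L[j, i] <- L[j, i] - 1
  }
  diag(L) <- adjacency$num
  L
}
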