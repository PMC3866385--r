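#' Generate a resting-state network phantom
#'
#' Builds the spatial scaffold for a synthetic voxel-level connectivity study:
#' a lattice of gray-matter network nodes partitioned into contiguous modules,
#' a set of module-boundary nodes labelled as white-matter adjacent, an optional
#' midline slab of nodes (the interhemispheric-fissure analogue that will carry
#' extra global-signal loading), optional dual-membership "bridge" nodes on
#' module boundaries, and auxiliary tissue masks (a deep white-matter sphere and
#' a ventricle block) placed on an extended lattice outside the network node
#' set. The phantom fixes geometry and ground-truth labels only; signal
#' amplitudes live in [signal_model()].
#'
#' Modules are formed by recursive bisection of the lattice along the longest
#' axis, which guarantees contiguous, near-equal blocks. White-matter-adjacent
#' nodes are drawn from module-boundary voxels, mirroring how gray-matter
#' voxels bordering major tracts sit at parcel edges. Midline nodes are the
#' voxels closest to the mid-plane of the first axis.
#'
#' @param dims Integer 3-vector of lattice sizes (voxels per axis).
#' @param n_modules Number of ground-truth modules (>= 1).
#' @param wm_adjacent_fraction Fraction of gray nodes labelled
#'   `gray_wm_adjacent`, chosen along module boundaries. In `[0, 1)`.
#' @param seed Integer seed; the phantom is deterministic given its arguments.
#' @param midline_fraction Fraction of gray nodes flagged as midline
#'   (interhemispheric analogue). Set 0 to disable.
#' @param bridge_fraction Fraction of gray nodes given a secondary module
#'   membership on a module boundary. Set 0 to disable.
#' @param wm_sphere_radius Radius (voxels) of the deep white-matter sphere mask.
#' @param ventricle_dim Edge length (voxels) of the cubic ventricle mask.
#'
#' @return An object of class `phantom`: a list with `dims`, `coords`
#'   (n x 3 integer matrix, 0-based), `tissue` (`"gray"` or
#'   `"gray_wm_adjacent"`), `true_module` (1-based integer), `second_module`
#'   (integer or `NA`), `midline` (logical), `n_nodes`, and `aux` (list of
#'   0-based coordinate matrices `white_matter_sphere`, `ventricle`). The
#'   whole-brain (parenchyma) mask is the union of the network nodes and the
#'   white-matter sphere; it excludes the ventricle mask.
#' @examples
#' ph <- generate_phantom(c(6, 6, 6), n_modules = 4, wm_adjacent_fraction = 0)
#' table(ph$true_module)
#' @export
generate_phantom <- function(dims, n_modules = 6, wm_adjacent_fraction = 0.08,
                             seed = 1L, midline_fraction = 0.1,
                             bridge_fraction = 0, wm_sphere_radius = 2,
                             ventricle_dim = 3) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) {
    stop("`dims` must be a 3-vector of positive lattice sizes.", call. = FALSE)
  }
  n <- prod(dims)
  if (n_modules < 1L || n < n_modules) {
    stop("Impossible geometry: need prod(dims) >= n_modules >= 1.", call. = FALSE)
  }
  if (wm_adjacent_fraction < 0 || wm_adjacent_fraction >= 1) {
    stop("`wm_adjacent_fraction` must lie in [0, 1).", call. = FALSE)
  }
  if (midline_fraction < 0 || midline_fraction >= 1 ||
      bridge_fraction < 0 || bridge_fraction >= 1) {
    stop("`midline_fraction` and `bridge_fraction` must lie in [0, 1).", call. = FALSE)
  }

  coords <- as.matrix(expand.grid(x = 0:(dims[1] - 1L),
                                  y = 0:(dims[2] - 1L),
                                  z = 0:(dims[3] - 1L)))
  storage.mode(coords) <- "integer"
  rownames(coords) <- NULL

  true_module <- split_lattice(coords, n_modules)

  # boundary nodes: any 6-neighbour in a different module
  boundary <- boundary_nodes(coords, dims, true_module)

  withr_seed(seed, {
    tissue <- rep("gray", n)
    n_wm <- floor(wm_adjacent_fraction * n)
    wm_idx <- integer(0)
    if (n_wm > 0) {
      pool <- boundary
      if (length(pool) < n_wm) pool <- union(pool, setdiff(seq_len(n), pool))
      wm_idx <- sort(sample(pool, n_wm))
      tissue[wm_idx] <- "gray_wm_adjacent"
    }

    midline <- rep(FALSE, n)
    n_mid <- floor(midline_fraction * n)
    if (n_mid > 0) {
      centre <- (dims[1] - 1) / 2
      cand <- setdiff(order(abs(coords[, 1] - centre), seq_len(n)), wm_idx)
      midline[cand[seq_len(min(n_mid, length(cand)))]] <- TRUE
    }

    second_module <- rep(NA_integer_, n)
    n_bridge <- floor(bridge_fraction * n)
    if (n_bridge > 0) {
      pool <- setdiff(boundary, c(wm_idx, which(midline)))
      if (length(pool) > 0) {
        b_idx <- sort(sample(pool, min(n_bridge, length(pool))))
        second_module[b_idx] <- vapply(b_idx, function(i) {
          nb <- lattice_neighbours(coords[i, ], dims)
          other <- setdiff(unique(true_module[nb]), true_module[i])
          if (length(other) == 0L) NA_integer_ else min(other)
        }, integer(1))
      }
    }
  })

  aux <- aux_masks(dims, wm_sphere_radius, ventricle_dim)

  # for every node: nearest foreign module and Manhattan distance to it,
  # the scaffold for spatially graded mixed membership at module borders
  neighbor_module <- rep(NA_integer_, n)
  boundary_dist <- rep(Inf, n)
  if (n_modules > 1L) {
    for (m in seq_len(n_modules)) {
      own <- which(true_module == m)
      other <- which(true_module != m)
      d <- manhattan_min(coords[own, , drop = FALSE], coords[other, , drop = FALSE])
      boundary_dist[own] <- d$dist
      neighbor_module[own] <- true_module[other[d$which]]
    }
  }

  structure(list(
    dims = dims,
    coords = coords,
    tissue = tissue,
    true_module = true_module,
    second_module = second_module,
    midline = midline,
    neighbor_module = neighbor_module,
    boundary_dist = boundary_dist,
    midline_dist = abs(coords[, 1] - (dims[1] - 1) / 2),
    n_nodes = n,
    aux = aux,
    n_modules = n_modules,
    seed = as.integer(seed)
  ), class = "phantom")
}

# recursive bisection into contiguous near-equal blocks
split_lattice <- function(coords, n_modules) {
  blocks <- list(seq_len(nrow(coords)))
  while (length(blocks) < n_modules) {
    sizes <- lengths(blocks)
    k <- which.max(sizes)
    idx <- blocks[[k]]
    if (length(idx) < 2L) stop("Impossible geometry: cannot split further.", call. = FALSE)
    ext <- apply(coords[idx, , drop = FALSE], 2, function(v) diff(range(v)))
    ax <- which.max(ext)
    v <- coords[idx, ax]
    cut <- stats::median(v)
    left <- idx[v <= cut]
    right <- idx[v > cut]
    if (length(right) == 0L) { # degenerate median; split by rank instead
      o <- idx[order(v, idx)]
      left <- o[seq_len(floor(length(o) / 2))]
      right <- setdiff(idx, left)
    }
    blocks <- append(blocks[-k], list(left, right))
  }
  # stable module ids ordered by smallest member index
  blocks <- blocks[order(vapply(blocks, min, integer(1)))]
  module <- integer(nrow(coords))
  for (m in seq_along(blocks)) module[blocks[[m]]] <- m
  module
}

lattice_neighbours <- function(xyz, dims) {
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nb <- sweep(steps, 2, xyz, "+")
  ok <- nb[, 1] >= 0 & nb[, 1] < dims[1] &
    nb[, 2] >= 0 & nb[, 2] < dims[2] &
    nb[, 3] >= 0 & nb[, 3] < dims[3]
  nb <- nb[ok, , drop = FALSE]
  1L + nb[, 1] + dims[1] * (nb[, 2] + dims[2] * nb[, 3])
}

boundary_nodes <- function(coords, dims, module) {
  which(vapply(seq_len(nrow(coords)), function(i) {
    any(module[lattice_neighbours(coords[i, ], dims)] != module[i])
  }, logical(1)))
}

# min Manhattan distance (and argmin) from each row of `a` to rows of `b`
manhattan_min <- function(a, b) {
  dist <- numeric(nrow(a))
  which_min <- integer(nrow(a))
  for (i in seq_len(nrow(a))) {
    d <- abs(b[, 1] - a[i, 1]) + abs(b[, 2] - a[i, 2]) + abs(b[, 3] - a[i, 3])
    which_min[i] <- which.min(d)
    dist[i] <- d[which_min[i]]
  }
  list(dist = dist, which = which_min)
}

aux_masks <- function(dims, wm_sphere_radius, ventricle_dim) {
  # auxiliary tissue voxels live in a slab above the network lattice (z offset),
  # guaranteeing disjointness from the network node set
  z0 <- dims[3] + 1L
  # centres clamped so every auxiliary voxel has nonnegative coordinates
  centre_wm <- c(max(wm_sphere_radius, floor(dims[1] / 2)),
                 max(wm_sphere_radius, floor(dims[2] / 2)),
                 z0 + wm_sphere_radius)
  rng <- -wm_sphere_radius:wm_sphere_radius
  ball <- as.matrix(expand.grid(x = rng, y = rng, z = rng))
  ball <- ball[rowSums(ball^2) <= wm_sphere_radius^2, , drop = FALSE]
  wm <- sweep(ball, 2, centre_wm, "+")

  # ventricle block sits in its own z-slab above the sphere, so the two
  # auxiliary masks can never collide whatever the lattice size
  v0 <- c(floor(dims[1] / 2), floor(dims[2] / 2),
          z0 + 2L * wm_sphere_radius + 2L)
  rngv <- 0:(ventricle_dim - 1L)
  vent <- as.matrix(expand.grid(x = rngv, y = rngv, z = rngv))
  vent <- sweep(vent, 2, v0, "+")
  if (nrow(wm) == 0L || nrow(vent) == 0L) {
    stop("Impossible geometry: empty auxiliary mask requested.", call. = FALSE)
  }
  storage.mode(wm) <- "integer"
  storage.mode(vent) <- "integer"
  list(white_matter_sphere = wm, ventricle = vent)
}

# run code with a local RNG state; restores the caller's stream afterwards
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> ", paste(x$dims, collapse = " x "),
      " lattice, ", x$n_nodes, " gray nodes, ",
      x$n_modules, " modules\n", sep = "")
  cat("  wm-adjacent: ", sum(x$tissue == "gray_wm_adjacent"),
      "; midline: ", sum(x$midline),
      "; bridge: ", sum(!is.na(x$second_module)), "\n", sep = "")
  cat("  aux voxels: wm sphere ", nrow(x$aux$white_matter_sphere),
      ", ventricle ", nrow(x$aux$ventricle), "\n", sep = "")
  invisible(x)
}
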