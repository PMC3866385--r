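#' Write and read node-by-time series as TSV
#'
#' Plain-text exchange format for headless runs: one row per node, one column
#' per time point, with node metadata (coordinates, tissue, module labels) in
#' leading columns. `read_timeseries_tsv()` restores a `ts_data` object
#' (without auxiliary masks, which live in their own file when written by
#' [write_phantom_tsv()]).
#'
#' @param dataset A `ts_data`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timeseries_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "ts_data"))
  meta <- tibble::tibble(
    x = dataset$coords[, 1], y = dataset$coords[, 2], z = dataset$coords[, 3],
    tissue = dataset$tissue, true_module = dataset$true_module,
    second_module = dataset$second_module, midline = dataset$midline
  )
  df <- dplyr::bind_cols(meta, tibble::as_tibble(dataset$data,
                                                 .name_repair = ~ paste0("t", seq_along(.x))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @param tr Sampling interval of the stored series (not serialized in the TSV).
#' @export
read_timeseries_tsv <- function(path, tr = 2.5) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta_cols <- c("x", "y", "z", "tissue", "true_module", "second_module", "midline")
  data <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  dimnames(data) <- NULL
  t_len <- ncol(data)
  structure(list(
    data = data, aux = matrix(numeric(0), 0, t_len), aux_label = character(0),
    motion = matrix(0, 6, t_len), tr = tr, t = t_len,
    tissue = df$tissue, true_module = df$true_module,
    second_module = df$second_module, midline = df$midline,
    coords = as.matrix(df[, c("x", "y", "z")]),
    latent = NULL, model = NULL, provenance = "read_timeseries_tsv"
  ), class = "ts_data")
}

#' Export nuisance series as TSV
#'
#' One column per regressor (six motion columns plus the three tissue means).
#'
#' @param nuisance A `nuisance_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nuisance_tsv <- function(nuisance, path) {
  stopifnot(inherits(nuisance, "nuisance_set"))
  df <- data.frame(t(nuisance$motion))
  names(df) <- paste0("motion", 1:6)
  df$whole_brain <- nuisance$whole_brain
  df$white_matter <- nuisance$white_matter
  df$ventricle <- nuisance$ventricle
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a binary network as an edge list with a JSON sidecar
#'
#' Writes `<prefix>_edges.tsv` (0-based node indices, one unordered edge per
#' row) and `<prefix>_network.json` recording `n`, `threshold`, `K`,
#' `S_achieved` and the edge rule.
#'
#' @param network A `binary_network`.
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_network <- function(network, prefix) {
  stopifnot(inherits(network, "binary_network"))
  el <- igraph::as_edgelist(network$graph, names = FALSE) - 1L
  edge_path <- paste0(prefix, "_edges.tsv")
  meta_path <- paste0(prefix, "_network.json")
  utils::write.table(data.frame(i = el[, 1], j = el[, 2]), edge_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n = network$n, threshold = network$threshold,
                            K = network$K, S_achieved = network$S_achieved,
                            edge_rule = network$edge_rule),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(edge_path, meta_path))
}

#' Export a partition as TSV
#'
#' Two columns: 0-based node id and module id (junk = 0).
#'
#' @param partition A `partition`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  stopifnot(inherits(partition, "partition"))
  utils::write.table(
    data.frame(node = seq_along(partition$module) - 1L,
               module = partition$module),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write phantom volumes as NIfTI-1
#'
#' Writes the phantom's label volumes (network mask, tissue labels, true
#' modules, auxiliary masks) and, if a dataset is supplied, the 4D series
#' volume, on the extended lattice that contains the auxiliary masks.
#'
#' @param phantom A `phantom`.
#' @param dir Output directory.
#' @param dataset Optional `ts_data` simulated from this phantom.
#' @return The written paths, invisibly.
#' @export
write_phantom_nifti <- function(phantom, dir, dataset = NULL) {
  all_coords <- rbind(phantom$coords, phantom$aux$white_matter_sphere,
                      phantom$aux$ventricle)
  ext <- apply(all_coords, 2, max) + 1L
  vol <- function(values_by_node, coords) {
    a <- array(0, dim = ext)
    a[cbind(coords[, 1] + 1L, coords[, 2] + 1L, coords[, 3] + 1L)] <- values_by_node
    a
  }
  n_aux_wm <- nrow(phantom$aux$white_matter_sphere)
  n_aux_v <- nrow(phantom$aux$ventricle)
  paths <- character(0)
  wr <- function(a, name) {
    p <- file.path(dir, name)
    RNifti::writeNifti(RNifti::asNifti(a), p)
    paths <<- c(paths, p)
  }
  wr(vol(rep(1, phantom$n_nodes), phantom$coords), "network_mask.nii.gz")
  wr(vol(as.integer(phantom$tissue == "gray_wm_adjacent") + 1L, phantom$coords),
     "tissue_labels.nii.gz")
  wr(vol(phantom$true_module, phantom$coords), "true_modules.nii.gz")
  wr(vol(rep(1, n_aux_wm), phantom$aux$white_matter_sphere), "wm_sphere_mask.nii.gz")
  wr(vol(rep(1, n_aux_v), phantom$aux$ventricle), "ventricle_mask.nii.gz")
  if (!is.null(dataset)) {
    t_len <- ncol(dataset$data)
    a4 <- array(0, dim = c(ext, t_len))
    idx <- cbind(phantom$coords[, 1] + 1L, phantom$coords[, 2] + 1L,
                 phantom$coords[, 3] + 1L)
    aux_idx <- rbind(phantom$aux$white_matter_sphere,
                     phantom$aux$ventricle) + 1L
    for (tt in seq_len(t_len)) {
      a4[cbind(idx, tt)] <- dataset$data[, tt]
      a4[cbind(aux_idx, tt)] <- dataset$aux[, tt]
    }
    p <- file.path(dir, "series.nii.gz")
    img <- RNifti::asNifti(a4)
    RNifti::pixdim(img) <- c(1, 1, 1, dataset$tr)
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write an overlap map as NIfTI-1
#'
#' @param map An `overlap_map`.
#' @param phantom The `phantom` supplying node coordinates.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_overlap_nifti <- function(map, phantom, path) {
  stopifnot(inherits(map, "overlap_map"), inherits(phantom, "phantom"))
  a <- array(0, dim = phantom$dims)
  a[cbind(phantom$coords[, 1] + 1L, phantom$coords[, 2] + 1L,
          phantom$coords[, 3] + 1L)] <- map$count
  RNifti::writeNifti(RNifti::asNifti(a), path)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' Reads a YAML (or JSON) file whose top-level keys are [study_config()]
#' arguments, with `model:` holding [signal_model()] arguments, and builds the
#' config. Unknown keys are an error, so typos do not silently fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(study_config)), "...")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("Unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$model)) {
    bad_m <- setdiff(names(raw$model), names(formals(signal_model)))
    if (length(bad_m)) {
      stop("Unknown model keys: ", paste(bad_m, collapse = ", "), call. = FALSE)
    }
  }
  do.call(study_config, raw)
}
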