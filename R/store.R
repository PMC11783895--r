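# Indexed HDF5 feature storage. Fixed-shape collections (voxels, images) are
# stored as slices of one dataset; variable-length collections (coordinates,
# surface vertices) are concatenated along the first dimension with start/end
# index datasets for constant-time random access:
#   /<rep>/data                  feature values (32-bit reals)
#   /<rep>/start, /<rep>/end     0-based entry offsets (heterogeneous only)
#   /labels                      integer class ids (0-based into /label_codes)
#   /label_codes                 class code strings
#   /topology/<code>/...         per-class atom names/elements

#' Create an empty fragment store
#' @param path HDF5 file path (must not exist).
#' @return A `fragment_store` handle.
#' @export
create_store <- function(path) {
  if (file.exists(path)) stop("store already exists: ", path)
  rhdf5::h5createFile(path)
  h <- structure(list(path = path, cache = new.env(parent = emptyenv())),
                 class = "fragment_store")
  h
}

#' Open an existing fragment store
#' @param path HDF5 file path.
#' @return A `fragment_store` handle.
#' @export
open_store <- function(path) {
  if (!file.exists(path)) stop("no such store: ", path)
  structure(list(path = path, cache = new.env(parent = emptyenv())),
            class = "fragment_store")
}

.store_ls <- function(store) {
  info <- rhdf5::h5ls(store$path)
  info
}

#' @export
print.fragment_store <- function(x, ...) {
  info <- .store_ls(x)
  reps <- unique(sub("^/", "", info$group[info$name == "data"]))
  cat(sprintf("<fragment_store %s: collections [%s], %d entries>\n", x$path,
              paste(reps, collapse = ", "),
              tryCatch(length(read_labels(x)), error = function(e) 0L)))
  invisible(x)
}

.h5_has <- function(store, name) {
  info <- .store_ls(store)
  name %in% paste0(sub("^/$", "", info$group), "/", info$name)
}

.write_labels <- function(store, labels) {
  labels <- toupper(as.character(labels))
  if (.h5_has(store, "/labels")) {
    existing <- read_labels(store)
    if (length(existing) != length(labels) || !all(existing == labels))
      stop("labels differ from those already in the store")
    return(invisible(store))
  }
  codes <- sort(unique(labels))
  ids <- match(labels, codes) - 1L
  rhdf5::h5write(ids, store$path, "labels")
  rhdf5::h5write(codes, store$path, "label_codes")
  invisible(store)
}

#' Read the class code of every entry
#' @param store A `fragment_store`.
#' @return Character vector of class codes.
#' @export
read_labels <- function(store) {
  ids <- as.integer(rhdf5::h5read(store$path, "labels"))
  codes <- as.character(rhdf5::h5read(store$path, "label_codes"))
  codes[ids + 1L]
}

#' Write a fixed-shape (homogeneous) feature collection
#'
#' Every entry must share one shape (e.g. 32x32x32 voxel grids or 128x128
#' images); entry `i` is stored as slice `i` of `/<name>/data` and is
#' retrievable in constant time.
#'
#' @param store A `fragment_store`.
#' @param name Collection name (e.g. `"voxel"`, `"hilbert"`).
#' @param entries List of equal-shape numeric arrays/matrices.
#' @param labels Class code per entry.
#' @return The store handle, invisibly.
#' @export
write_homogeneous <- function(store, name, entries, labels) {
  stopifnot(length(entries) == length(labels), length(entries) >= 1)
  shp <- dim(entries[[1]]) %||% length(entries[[1]])
  for (e in entries)
    if (!identical(dim(e) %||% length(e), shp))
      stop("write_homogeneous: entries have mixed shapes")
  n <- length(entries)
  arr <- array(unlist(entries, use.names = FALSE), dim = c(shp, n))
  .write_labels(store, labels)
  ds <- paste0(name, "/data")
  if (.h5_has(store, paste0("/", ds))) stop("collection exists: ", name)
  rhdf5::h5createGroup(store$path, name)
  rhdf5::h5createDataset(store$path, ds, dims = c(shp, n),
                         H5type = "H5T_IEEE_F32LE", chunk = c(shp, 1))
  rhdf5::h5write(arr, store$path, ds)
  rhdf5::h5write("homogeneous", store$path, paste0(name, "/kind"))
  invisible(store)
}

#' Write a variable-length (heterogeneous) feature collection
#'
#' Entries are matrices with a common second dimension (e.g. n_i x 3
#' coordinates); they are concatenated along the first dimension and 0-based
#' `start`/`end` offsets are recorded so entry `i` is the rows
#' `(start[i], end[i]]` of `/<name>/data`.
#'
#' @inheritParams write_homogeneous
#' @param entries List of matrices with identical column count.
#' @return The store handle, invisibly.
#' @export
write_heterogeneous <- function(store, name, entries, labels) {
  stopifnot(length(entries) == length(labels), length(entries) >= 1)
  entries <- lapply(entries, function(e) {
    e <- as.matrix(e)
    if (ncol(e) != ncol(as.matrix(entries[[1]])))
      stop("write_heterogeneous: inconsistent second dimension")
    e
  })
  lens <- vapply(entries, nrow, 0L)
  start <- cumsum(c(0L, lens[-length(lens)]))
  end <- cumsum(lens)
  .write_labels(store, labels)
  if (.h5_has(store, paste0("/", name, "/data")))
    stop("collection exists: ", name)
  rhdf5::h5createGroup(store$path, name)
  dat <- do.call(rbind, entries)
  ds <- paste0(name, "/data")
  rhdf5::h5createDataset(store$path, ds, dims = dim(dat),
                         H5type = "H5T_IEEE_F32LE", chunk = c(min(nrow(dat), 4096L), ncol(dat)))
  rhdf5::h5write(dat, store$path, ds)
  rhdf5::h5write(as.integer(start), store$path, paste0(name, "/start"))
  rhdf5::h5write(as.integer(end), store$path, paste0(name, "/end"))
  rhdf5::h5write("heterogeneous", store$path, paste0(name, "/kind"))
  invisible(store)
}

.collection_meta <- function(store, name) {
  key <- paste0("meta:", name)
  m <- store$cache[[key]]
  if (!is.null(m)) return(m)
  if (!.h5_has(store, paste0("/", name, "/data")))
    stop("unknown collection: ", name)
  kind <- as.character(rhdf5::h5read(store$path, paste0(name, "/kind")))
  if (kind == "heterogeneous") {
    start <- as.integer(rhdf5::h5read(store$path, paste0(name, "/start")))
    end <- as.integer(rhdf5::h5read(store$path, paste0(name, "/end")))
    m <- list(kind = kind, start = start, end = end, n = length(start))
  } else {
    info <- .store_ls(store)
    row <- info[paste0(sub("^/$", "", info$group), "/", info$name) ==
                  paste0("/", name, "/data"), ]
    dims <- as.integer(strsplit(row$dim, " x ")[[1]])
    m <- list(kind = kind, shape = dims[-length(dims)], n = dims[length(dims)])
  }
  store$cache[[key]] <- m
  m
}

#' Number of entries in a collection
#' @param store A `fragment_store`.
#' @param name Collection name.
#' @return Integer count.
#' @export
n_entries <- function(store, name) .collection_meta(store, name)$n

#' Read one entry from a collection
#'
#' Constant-time random access: one index lookup plus one contiguous read,
#' independent of the entry position.
#'
#' @param store A `fragment_store`.
#' @param name Collection name.
#' @param i 1-based entry index.
#' @return The entry (array for homogeneous, matrix for heterogeneous).
#' @export
read_entry <- function(store, name, i) {
  m <- .collection_meta(store, name)
  if (i < 1 || i > m$n) stop("entry index out of range: ", i)
  ds <- paste0(name, "/data")
  if (m$kind == "heterogeneous") {
    rows <- (m$start[i] + 1L):m$end[i]
    out <- rhdf5::h5read(store$path, ds, index = list(rows, NULL))
  } else {
    idx <- c(lapply(m$shape, function(d) NULL), list(i))
    out <- rhdf5::h5read(store$path, ds, index = idx)
    out <- array(out, dim = m$shape)
  }
  out
}

#' Iterate a collection in shuffled batches
#'
#' Returns an iterator closure; each call yields `list(features, labels,
#' indices)` until the epoch is exhausted (then `NULL`). The visit order is a
#' seed-determined permutation covering every entry exactly once per epoch;
#' the worker count only parallelizes reading (fork-based) and never changes
#' the yielded content.
#'
#' @param store A `fragment_store`.
#' @param name Collection name.
#' @param batch_size Entries per batch (>= 1).
#' @param workers Reader processes (>= 1).
#' @param seed Shuffle seed.
#' @return A function; call repeatedly to obtain batches.
#' @export
iterate_batches <- function(store, name, batch_size, workers = 1L, seed = 1L) {
  stopifnot(batch_size >= 1, workers >= 1)
  m <- .collection_meta(store, name)
  labels <- read_labels(store)
  ord <- .with_seed(seed, sample.int(m$n))
  batches <- split(ord, ceiling(seq_along(ord) / batch_size))
  bi <- 0L
  read_one <- function(idx) {
    feats <- lapply(idx, function(i) read_entry(store, name, i))
    list(features = feats, labels = labels[idx], indices = idx)
  }
  function() {
    bi <<- bi + 1L
    if (bi > length(batches)) return(NULL)
    idx <- batches[[bi]]
    if (workers > 1L && length(idx) >= workers &&
        .Platform$OS.type == "unix") {
      chunks <- split(idx, cut(seq_along(idx), workers, labels = FALSE))
      parts <- parallel::mclapply(chunks, read_one, mc.cores = workers)
      list(features = unname(do.call(c, lapply(parts, `[[`, "features"))),
           labels = unname(unlist(lapply(parts, `[[`, "labels"))),
           indices = unname(unlist(lapply(parts, `[[`, "indices"))))
    } else read_one(idx)
  }
}

#' Benchmark retrieval throughput of a collection
#'
#' Times full shuffled epochs through [iterate_batches()] and reports sample
#' and bit throughput (entries are 32-bit reals on disk).
#'
#' @param store A `fragment_store`.
#' @param name Collection name.
#' @param cores Reader processes.
#' @param batch_size Batch size (the retrieval benchmark convention is 128).
#' @param repeats Number of timed epochs (convention: 10).
#' @param seed Shuffle seed.
#' @return List: `samples_per_s`, `bits_per_s`, `mean_epoch_time`,
#'   `epoch_times`, `entry_bits`.
#' @export
benchmark_throughput <- function(store, name, cores = 1L, batch_size = 128L,
                                 repeats = 10L, seed = 1L) {
  m <- .collection_meta(store, name)
  entry_values <- if (m$kind == "heterogeneous")
    mean(m$end - m$start) * ncol(read_entry(store, name, 1L))
  else prod(m$shape)
  entry_bits <- entry_values * 32
  times <- numeric(repeats)
  for (r in seq_len(repeats)) {
    it <- iterate_batches(store, name, batch_size, workers = cores,
                          seed = seed + r)
    t0 <- proc.time()[["elapsed"]]
    while (!is.null(b <- it())) {}
    times[r] <- proc.time()[["elapsed"]] - t0
  }
  sps <- m$n / mean(times)
  list(samples_per_s = sps, bits_per_s = sps * entry_bits,
       mean_epoch_time = mean(times), epoch_times = times,
       entry_bits = entry_bits)
}

#' Write completed fragments (raw coordinates) into a store
#'
#' Stores coordinates as the heterogeneous collection `"coord"`, labels, and
#' one topology record (atom names/elements) per class.
#'
#' @param store A `fragment_store`.
#' @param frags List of completed `fragment` objects.
#' @return The store handle, invisibly.
#' @export
write_fragments <- function(store, frags) {
  labels <- vapply(frags, `[[`, "", "label")
  write_heterogeneous(store, "coord", lapply(frags, `[[`, "coords"), labels)
  rhdf5::h5createGroup(store$path, "topology")
  for (code in unique(labels)) {
    fr <- frags[[match(code, labels)]]
    grp <- paste0("topology/", code)
    rhdf5::h5createGroup(store$path, grp)
    rhdf5::h5write(fr$atom_names, store$path, paste0(grp, "/atom_names"))
    rhdf5::h5write(fr$elements, store$path, paste0(grp, "/elements"))
    rhdf5::h5write(as.integer(fr$res), store$path, paste0(grp, "/res"))
  }
  invisible(store)
}

#' Read one stored fragment back from the `"coord"` collection
#' @param store A `fragment_store`.
#' @param i 1-based entry index.
#' @return A `fragment`.
#' @export
read_fragment <- function(store, i) {
  lab <- read_labels(store)[i]
  co <- read_entry(store, "coord", i)
  grp <- paste0("topology/", lab)
  fragment(lab,
           as.character(rhdf5::h5read(store$path, paste0(grp, "/atom_names"))),
           as.character(rhdf5::h5read(store$path, paste0(grp, "/elements"))),
           co,
           res = as.integer(rhdf5::h5read(store$path, paste0(grp, "/res"))),
           source_id = sprintf("%s#%d", store$path, i))
}

#' Featurize a stored coordinate collection
#'
#' Reads every fragment from `"coord"` and writes the requested
#' representation as a new collection: `"voxel"` (32^3 grids), `"hilbert"`
#' (128x128 images), `"coord_pc"` (prepared point clouds, homogeneous
#' K x 3), or `"surf_pc"` (surface-vertex point clouds, K x 3).
#'
#' @param store A `fragment_store` holding a `"coord"` collection.
#' @param rep One of `"voxel"`, `"hilbert"`, `"coord_pc"`, `"surf_pc"`.
#' @param target_points Point count for point-cloud reps (24/42 for raw
#'   coordinates, 1500 for surfaces).
#' @param seed Seed for point-cloud preparation.
#' @param params Voxelization parameters.
#' @return The store handle, invisibly.
#' @export
featurize_store <- function(store, rep = c("voxel", "hilbert", "coord_pc",
                                           "surf_pc"),
                            target_points = 24L, seed = 1L,
                            params = voxel_params()) {
  rep <- match.arg(rep)
  n <- n_entries(store, "coord")
  labels <- read_labels(store)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- read_fragment(store, i)
    entries[[i]] <- switch(rep,
      voxel = unclass(voxelize(fr, params)),
      hilbert = unclass(make_hilbert_image(voxelize(fr, params))),
      coord_pc = unclass(prepare_pointcloud(fr, target_points,
                                            seed = seed + i)),
      surf_pc = unclass(prepare_pointcloud(compute_surface(fr),
                                           target_points, seed = seed + i)))
  }
  write_homogeneous(store, rep, entries, labels)
  invisible(store)
}
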