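# Conformation-blocked train/test splitting. Per class: cap and superpose the
# conformers (all heavy atoms, Kabsch), Butina-cluster the pairwise RMSD
# matrix at 75% of its mean, route the bottom quartile of the size-sorted
# cluster list entirely to the test set, subdivide large clusters (t-SNE
# embedding of the RMSD metric + agglomerative subclustering) and draw
# balanced selections, and give small clusters a random 2:1 split of at most
# 15 samples. The test set is thereby populated with lower-likelihood
# conformations and train/test conformational overlap is reduced.

#' All-pairs minimal RMSD matrix of a conformer set
#'
#' Superposes every pair on all heavy atoms (optimal rotation + translation)
#' and returns the symmetric RMSD matrix. At most `cap` conformers are used
#' (random subset, seed-determined) when the input is larger.
#'
#' @param fragments List of completed `fragment` objects of one class.
#' @param cap Maximum number of conformers (default 5000).
#' @param seed Subset seed.
#' @return Symmetric matrix with zero diagonal; attribute `"subset"` records
#'   the indices used.
#' @export
pairwise_rmsd <- function(fragments, cap = 5000L, seed = 1L) {
  labs <- vapply(fragments, `[[`, "", "label")
  if (length(unique(labs)) != 1)
    stop("pairwise_rmsd: fragments must all belong to one class")
  idx <- seq_along(fragments)
  if (length(idx) > cap)
    idx <- sort(.with_seed(seed, sample.int(length(idx), cap)))
  heavy <- fragments[[idx[1]]]$elements != "H"
  m <- sum(heavy)
  cmat <- vapply(idx, function(i) {
    co <- fragments[[i]]$coords[heavy, , drop = FALSE]
    as.numeric(t(co))
  }, numeric(3 * m))
  out <- .pairwise_rmsd_cpp(cmat, m)
  attr(out, "subset") <- idx
  out
}

#' Butina (leader) clustering of a distance matrix
#'
#' Repeatedly picks the sample with the most unassigned neighbors within
#' `threshold` as a cluster centroid and assigns those neighbors to it.
#' Returned clusters are sorted by decreasing size (ties: discovery order).
#'
#' @param dist Symmetric numeric matrix with zero diagonal.
#' @param threshold Neighborhood radius (same units as `dist`).
#' @return List of integer index vectors, one per cluster; every sample
#'   appears in exactly one cluster.
#' @export
butina_cluster <- function(dist, threshold) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist) || max(abs(dist - t(dist))) > 1e-8)
    stop("butina_cluster: distance matrix must be symmetric")
  if (threshold < 0) stop("threshold must be >= 0")
  n <- nrow(dist)
  unassigned <- rep(TRUE, n)
  nbr <- dist <= threshold
  clusters <- list()
  while (any(unassigned)) {
    cnt <- colSums(nbr[unassigned, , drop = FALSE])
    cnt[!unassigned] <- -1
    centroid <- which.max(cnt)
    members <- which(nbr[, centroid] & unassigned)
    members <- union(centroid, members)
    clusters[[length(clusters) + 1L]] <- members
    unassigned[members] <- FALSE
  }
  sizes <- lengths(clusters)
  clusters[order(-sizes)]
}

#' Subdivide one cluster by 2D embedding + agglomerative clustering
#'
#' Embeds the precomputed RMSD sub-matrix into two dimensions with t-SNE
#' (distance input) and cuts a Ward agglomerative tree of the embedding into
#' `k` subclusters. Deterministic given `seed`.
#'
#' @param dist_sub Distance sub-matrix of the cluster members.
#' @param k Number of subclusters (default 10).
#' @param seed RNG seed for the embedding.
#' @return Integer vector of subcluster labels (1..k).
#' @export
subcluster <- function(dist_sub, k = 10L, seed = 1L) {
  dist_sub <- as.matrix(dist_sub)
  n <- nrow(dist_sub)
  if (n <= k) stop("cluster too small to subdivide into ", k)
  emb <- .with_seed(seed, {
    perp <- max(1, min(30, floor((n - 1) / 3)))
    Rtsne::Rtsne(stats::as.dist(dist_sub), perplexity = perp, theta = 0.0,
                 max_iter = 350, is_distance = TRUE, pca = FALSE,
                 check_duplicates = FALSE)$Y
  })
  hc <- stats::hclust(stats::dist(emb), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Conformation-blocked baseline split of one class
#'
#' @param fragments List of completed `fragment` objects of one class (or a
#'   precomputed distance matrix via `dist`).
#' @param seed RNG seed controlling capping, subsampling and 2:1 splits.
#' @param cap Conformer cap before the RMSD matrix (5000).
#' @param threshold_factor Butina threshold as a fraction of the mean
#'   off-diagonal RMSD (0.75).
#' @param bottom_fraction Fraction of the size-sorted cluster list routed
#'   entirely to test (0.25).
#' @param size_gate Cluster size above which subclustering applies (30).
#' @param k_sub Number of subclusters (10).
#' @param max_train,max_test Per-cluster selection caps (10 and 5).
#' @param small_max Small-cluster 2:1 split size cap (15).
#' @param dist Optional precomputed symmetric RMSD matrix.
#' @return A data frame of class `split_assignment`: sample, label,
#'   assignment (train/test/excluded), cluster, subcluster; parameters and
#'   threshold as attributes. Samples beyond the cap are `excluded` with
#'   cluster `NA`.
#' @export
build_baseline_split <- function(fragments, seed = 1L, cap = 5000L,
                                 threshold_factor = 0.75,
                                 bottom_fraction = 0.25, size_gate = 30L,
                                 k_sub = 10L, max_train = 10L, max_test = 5L,
                                 small_max = 15L, dist = NULL) {
  if (is.null(dist)) {
    if (length(fragments) < 2) stop("need at least 2 fragments")
    label <- fragments[[1]]$label
    D <- pairwise_rmsd(fragments, cap = cap, seed = seed)
    subset <- attr(D, "subset")
    n_all <- length(fragments)
  } else {
    D <- as.matrix(dist)
    subset <- seq_len(nrow(D))
    n_all <- nrow(D)
    label <- if (!missing(fragments) && length(fragments))
      fragments[[1]]$label else "?"
  }
  n <- nrow(D)
  assignment <- rep("excluded", n_all)
  cluster_id <- rep(NA_integer_, n_all)
  sub_id <- rep(NA_integer_, n_all)
  off <- D[upper.tri(D)]
  mean_rmsd <- if (length(off)) mean(off) else 0
  thr <- threshold_factor * mean_rmsd
  degenerate <- mean_rmsd < 1e-6
  if (degenerate) {
    warning("degenerate ensemble (mean RMSD ~ 0): routed to the small-cluster 2:1 path")
    clusters <- list(seq_len(n))
    bottom <- integer(0)
  } else {
    clusters <- butina_cluster(D, thr)
    n_bottom <- floor(bottom_fraction * length(clusters))
    bottom <- if (n_bottom > 0)
      seq(length(clusters) - n_bottom + 1L, length(clusters)) else integer(0)
  }
  .with_seed(seed + 1L, {
    for (ci in seq_along(clusters)) {
      mem <- clusters[[ci]]                   # indices into the capped subset
      gmem <- subset[mem]                     # global indices
      cluster_id[gmem] <- ci
      if (ci %in% bottom) {
        assignment[gmem] <- "test"
        next
      }
      if (!degenerate && length(mem) > size_gate) {
        sc <- subcluster(D[mem, mem, drop = FALSE], k = k_sub,
                         seed = seed + ci)
        sub_id[gmem] <- sc
        # up to max_train picks per subcluster, ordered by subcluster size
        sizes <- table(sc)
        picks <- integer(0)
        pick_sub <- integer(0)
        for (s in order(-sizes)) {
          smem <- mem[sc == s]
          take <- sample(smem, min(length(smem), max_train))
          picks <- c(picks, take)
          pick_sub <- c(pick_sub, rep(s, length(take)))
        }
        n_sel <- length(picks)
        n_train_pool <- ceiling(2 / 3 * n_sel)
        train_pool <- picks[seq_len(n_train_pool)]
        test_pool <- picks[setdiff(seq_len(n_sel), seq_len(n_train_pool))]
        tr <- head(train_pool, max_train)
        te <- head(test_pool, max_test)
        assignment[subset[tr]] <- "train"
        assignment[subset[te]] <- "test"
      } else {
        m <- min(small_max, length(mem))
        sel <- sample(mem, m)
        n_tr <- round(2 / 3 * m)
        assignment[subset[sel[seq_len(n_tr)]]] <- "train"
        if (m > n_tr)
          assignment[subset[sel[(n_tr + 1L):m]]] <- "test"
      }
    }
  })
  out <- data.frame(sample = seq_len(n_all),
                    label = label,
                    assignment = factor(assignment,
                                        levels = c("train", "test", "excluded")),
                    cluster = cluster_id, subcluster = sub_id,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  attr(out, "mean_rmsd") <- mean_rmsd
  attr(out, "params") <- list(cap = cap, threshold_factor = threshold_factor,
                              bottom_fraction = bottom_fraction,
                              size_gate = size_gate, k_sub = k_sub,
                              max_train = max_train, max_test = max_test,
                              small_max = small_max, seed = seed)
  class(out) <- c("split_assignment", class(out))
  out
}

#' Uniform random split with given set sizes
#'
#' Size-matched control for the blocked split: assigns `n_train` and `n_test`
#' samples at random, the rest excluded.
#'
#' @param n Number of samples.
#' @param n_train,n_test Set sizes.
#' @param seed RNG seed.
#' @return A `split_assignment` data frame (cluster columns `NA`).
#' @export
build_random_split <- function(n, n_train, n_test, seed = 1L) {
  if (n_train + n_test > n) stop("set sizes exceed sample count")
  assignment <- rep("excluded", n)
  .with_seed(seed, {
    sel <- sample.int(n, n_train + n_test)
    assignment[sel[seq_len(n_train)]] <- "train"
    assignment[sel[(n_train + 1L):(n_train + n_test)]] <- "test"
  })
  out <- data.frame(sample = seq_len(n), label = "?",
                    assignment = factor(assignment,
                                        levels = c("train", "test", "excluded")),
                    cluster = NA_integer_, subcluster = NA_integer_)
  class(out) <- c("split_assignment", class(out))
  out
}

#' Minimum cross-set RMSD between test and train conformers
#'
#' The blocking efficacy measure: for every test sample, the distance to its
#' nearest train sample, summarized by the minimum (or mean) over test
#' samples. Larger values mean less train/test conformational overlap.
#'
#' @param dist Symmetric RMSD matrix over all samples.
#' @param split A `split_assignment` for the same samples.
#' @param summary `"min"` or `"mean"` over test samples.
#' @return Nonnegative scalar.
#' @export
cross_set_rmsd <- function(dist, split, summary = c("min", "mean")) {
  summary <- match.arg(summary)
  tr <- which(split$assignment == "train")
  te <- which(split$assignment == "test")
  if (!length(tr) || !length(te)) return(NA_real_)
  nearest <- apply(as.matrix(dist)[te, tr, drop = FALSE], 1, min)
  if (summary == "min") min(nearest) else mean(nearest)
}

#' Write a split manifest as JSON
#'
#' Records the per-sample assignments together with the clustering parameters
#' actually used, for reproducibility.
#'
#' @param split A `split_assignment`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write manifests")
  payload <- list(parameters = attr(split, "params"),
                  threshold = attr(split, "threshold"),
                  mean_rmsd = attr(split, "mean_rmsd"),
                  assignments = as.data.frame(split))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
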