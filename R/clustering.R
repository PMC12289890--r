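#' Clustering parameters for mark aggregation
#'
#' Parameters shared by the density-based counting methods. The minimum
#' cluster size defaults to 5, tied to the minimum agreement threshold: a
#' cluster of marks is counted as an animal only if at least five
#' volunteers placed a mark there.
#'
#' @param min_cluster_size Minimum marks per counted cluster (>= 2).
#' @param min_samples Neighbourhood size for core-distance/core-point
#'   computations (defaults to `min_cluster_size`).
#' @param eps DBSCAN reachability radius, in pixels.
#' @param allow_single_cluster Let HDBSCAN return the root cluster when the
#'   hierarchy never splits into two viable clusters. Required here:
#'   most occupied tiles hold a single animal, whose marks form exactly one
#'   cluster.
#' @return Validated list of class `"clustering_params"`.
#' @export
clustering_params <- function(min_cluster_size = 5L,
                              min_samples = min_cluster_size,
                              eps = 30,
                              allow_single_cluster = TRUE) {
  if (min_cluster_size < 2) stop("min_cluster_size must be >= 2",
                                 call. = FALSE)
  if (min_samples < 1) stop("min_samples must be >= 1", call. = FALSE)
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  structure(list(min_cluster_size = as.integer(min_cluster_size),
                 min_samples = as.integer(min_samples), eps = eps,
                 allow_single_cluster = isTRUE(allow_single_cluster)),
            class = "clustering_params")
}

#' DBSCAN labels for a 2-d point set
#'
#' Classical density-based clustering with Euclidean distances: a point is
#' a core point when at least `min_samples` points (itself included) lie
#' within `eps`; clusters are the connected components of core points,
#' plus border points attached to a neighbouring core point. Noise is
#' labelled 0.
#'
#' @param xy Two-column matrix or data frame of coordinates.
#' @param eps Reachability radius.
#' @param min_samples Neighbourhood size making a point core (the point
#'   itself counts).
#' @return Integer vector of cluster labels (0 = noise).
#' @export
dbscan_labels <- function(xy, eps, min_samples) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n == 0) return(integer(0))
  D <- as.matrix(stats::dist(xy))
  nbr <- D <= eps
  core <- rowSums(nbr) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      reach <- which(nbr[p, ] & labels == 0L)
      if (length(reach)) {
        labels[reach] <- cl
        queue <- c(queue, reach[core[reach]])
      }
    }
  }
  # border points grabbed by a non-core expansion step above are fine;
  # points never reached from a core point remain noise (0)
  labels
}

#' HDBSCAN labels for a 2-d point set
#'
#' Hierarchical density-based clustering: mutual-reachability distances
#' (from `min_samples`-nearest-neighbour core distances) feed a
#' single-linkage hierarchy, which is condensed with the minimum cluster
#' size; clusters are then selected by excess-of-mass stability. With
#' `allow_single_cluster` the hierarchy root competes for selection, so a
#' point set forming one coherent cluster yields one cluster rather than
#' none.
#'
#' @inheritParams dbscan_labels
#' @param min_cluster_size Minimum points for a condensed cluster.
#' @param allow_single_cluster Allow the root cluster to be selected.
#' @return Integer vector of cluster labels (0 = noise).
#' @export
hdbscan_labels <- function(xy, min_cluster_size = 5L,
                           min_samples = min_cluster_size,
                           allow_single_cluster = TRUE) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < min_cluster_size) return(integer(n))
  D <- as.matrix(stats::dist(xy))
  k <- min(min_samples, n)
  core <- apply(D, 1, function(r) sort(r, partial = k)[k])
  mreach <- pmax(D, outer(core, core, pmax))
  hc <- stats::hclust(stats::as.dist(mreach), method = "single")
  condensed <- condense_tree(hc, n, min_cluster_size)
  selected <- select_clusters_eom(condensed, allow_single_cluster)
  label_points(condensed, selected, n)
}

# --- condensed-tree machinery -------------------------------------------
# The single-linkage dendrogram is walked from the root. At each merge
# height h (lambda = 1/h, floored so coincident points stay finite), a
# split is "real" when both sides hold >= min_cluster_size points: the
# current cluster ends there and two children are born. Smaller sides fall
# out of the running cluster, accruing its stability
# sum_p (lambda_leave(p) - lambda_birth).

condense_tree <- function(hc, n, m) {
  merge <- hc$merge
  h <- hc$height
  nint <- nrow(merge)
  # subtree size and member list per internal node
  size <- integer(nint)
  members <- vector("list", nint)
  for (i in seq_len(nint)) {
    mem <- integer(0)
    for (ch in merge[i, ]) {
      mem <- c(mem, if (ch < 0) -ch else members[[ch]])
    }
    members[[i]] <- mem
    size[i] <- length(mem)
  }
  lam <- 1 / pmax(h, 1e-10)
  env <- new.env()
  env$birth <- 0; env$stability <- 0; env$parent <- NA_integer_
  env$children <- list(integer(0))
  env$fall_cluster <- integer(n); env$fall_lambda <- numeric(n)
  node_size <- function(ch) if (ch < 0) 1L else size[ch]
  node_members <- function(ch) if (ch < 0) -ch else members[[ch]]
  walk <- function(node, cid) {
    repeat {
      l <- lam[node]
      ch <- merge[node, ]
      s <- c(node_size(ch[1]), node_size(ch[2]))
      big <- s >= m
      if (all(big)) {
        env$stability[cid] <- env$stability[cid] +
          sum(s) * (l - env$birth[cid])
        kids <- integer(2)
        for (j in 1:2) {
          ncid <- length(env$birth) + 1L
          env$birth[ncid] <- l
          env$stability[ncid] <- 0
          env$parent[ncid] <- cid
          env$children[[ncid]] <- integer(0)
          kids[j] <- ncid
          walk(ch[j], ncid)
        }
        env$children[[cid]] <- kids
        return(invisible())
      }
      if (any(big)) {
        small <- which(!big)
        pts <- node_members(ch[small])
        env$stability[cid] <- env$stability[cid] +
          length(pts) * (l - env$birth[cid])
        env$fall_cluster[pts] <- cid
        env$fall_lambda[pts] <- l
        node <- ch[which(big)]       # continue down the large side
        next
      }
      # both sides below the minimum: the cluster ends here
      pts <- c(node_members(ch[1]), node_members(ch[2]))
      env$stability[cid] <- env$stability[cid] +
        length(pts) * (l - env$birth[cid])
      env$fall_cluster[pts] <- cid
      env$fall_lambda[pts] <- l
      return(invisible())
    }
  }
  walk(nint, 1L)
  list(birth = env$birth, stability = env$stability, parent = env$parent,
       children = env$children, fall_cluster = env$fall_cluster,
       fall_lambda = env$fall_lambda)
}

# excess-of-mass selection: a cluster is kept when its stability is at
# least the summed stability of its selected descendants (ties prefer the
# parent); without allow_single_cluster the root never competes
select_clusters_eom <- function(cond, allow_single_cluster) {
  nc <- length(cond$birth)
  selected <- logical(nc)
  unselect_descendants <- function(cid) {
    for (ch in cond$children[[cid]]) {
      selected[ch] <<- FALSE
      unselect_descendants(ch)
    }
  }
  score <- function(cid) {
    kids <- cond$children[[cid]]
    root <- is.na(cond$parent[cid])
    if (length(kids) == 0) {
      if (!root || allow_single_cluster) selected[cid] <<- TRUE
      return(cond$stability[cid])
    }
    sc <- sum(vapply(kids, score, numeric(1)))
    if ((!root || allow_single_cluster) && cond$stability[cid] >= sc) {
      selected[cid] <<- TRUE
      unselect_descendants(cid)
      return(cond$stability[cid])
    }
    sc
  }
  score(1L)
  which(selected)
}

# a point belongs to the selected cluster among the cluster it fell out of
# and that cluster's ancestors; otherwise it is noise
label_points <- function(cond, selected, n) {
  labels <- integer(n)
  lab_of <- integer(length(cond$birth))
  lab_of[selected] <- seq_along(selected)
  for (p in seq_len(n)) {
    cid <- cond$fall_cluster[p]
    while (!is.na(cid) && cid >= 1) {
      if (lab_of[cid] > 0) { labels[p] <- lab_of[cid]; break }
      cid <- cond$parent[cid]
    }
  }
  labels
}

#' Count animals by clustering pooled volunteer marks
#'
#' Pools the (countable) marks of all volunteers for one image and counts
#' the density clusters; each cluster with enough support represents one
#' animal. Noise marks belong to no cluster and are not counted. With
#' fewer than `min_cluster_size` pooled marks the count is 0.
#'
#' @param marks Two-column matrix/data frame of mark coordinates
#'   (partial-category marks already excluded).
#' @param method `"dbscan"` or `"hdbscan"`.
#' @param params A [clustering_params()].
#' @return List with `count`, `centroids` (one row per cluster) and the
#'   point `labels`.
#' @export
cluster_count <- function(marks, method = c("hdbscan", "dbscan"),
                          params = clustering_params()) {
  method <- match.arg(method)
  xy <- as.matrix(marks)
  if (nrow(xy) < params$min_cluster_size) {
    return(list(count = 0L,
                centroids = matrix(numeric(0), 0, 2,
                                   dimnames = list(NULL, c("x", "y"))),
                labels = integer(nrow(xy))))
  }
  labels <- if (method == "dbscan") {
    dbscan_labels(xy, eps = params$eps, min_samples = params$min_samples)
  } else {
    hdbscan_labels(xy, min_cluster_size = params$min_cluster_size,
                   min_samples = params$min_samples,
                   allow_single_cluster = params$allow_single_cluster)
  }
  ks <- sort(unique(labels[labels > 0]))
  centroids <- t(vapply(ks, function(k) colMeans(xy[labels == k, , drop = FALSE]),
                        numeric(2)))
  if (length(ks) == 0) {
    centroids <- matrix(numeric(0), 0, 2)
  }
  colnames(centroids) <- c("x", "y")
  list(count = length(ks), centroids = centroids, labels = labels)
}
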