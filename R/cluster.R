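#' Channel adjacency graph from a montage
#'
#' Two channels are neighbours when their chord (3D straight-line) distance
#' is at or below the given quantile of all pairwise distances. The default
#' quantile (0.10) gives a median degree of about 7 on the packaged
#' 64-channel montage.
#'
#' @param montage a [make_montage()] result (or subset).
#' @param distance_quantile quantile in `[0, 1]`; 0 gives an empty edge
#'   set, 1 the complete graph.
#' @return An object of class `adjacency`: `labels` and `neighbors` (list
#'   of integer vectors, symmetric, no self-edges).
#' @export
build_adjacency <- function(montage, distance_quantile = 0.10) {
  stopifnot(inherits(montage, "montage"))
  if (distance_quantile < 0 || distance_quantile > 1)
    stop("distance_quantile must lie in [0, 1]")
  n <- nrow(montage)
  d <- as.matrix(stats::dist(as.matrix(montage[, c("x", "y", "z")])))
  nb <- vector("list", n)
  if (distance_quantile == 0) {
    nb <- replicate(n, integer(0), simplify = FALSE)
  } else {
    thr <- stats::quantile(d[upper.tri(d)], distance_quantile, names = FALSE)
    adj <- d <= thr
    diag(adj) <- FALSE
    nb <- lapply(seq_len(n), function(i) which(adj[i, ]))
  }
  structure(list(labels = montage$label, neighbors = nb),
            class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("adjacency: %d nodes, %d edges, median degree %g\n",
              length(x$labels), sum(deg) / 2, stats::median(deg)))
  invisible(x)
}

#' Channel-pair adjacency for connectivity cluster tests
#'
#' Lifts a channel adjacency to the space of unordered channel pairs: two
#' pairs are neighbours when they share one channel and the other two
#' channels are montage neighbours.
#'
#' @param adjacency a [build_adjacency()] result.
#' @return An `adjacency` whose nodes are channel pairs labelled
#'   `"A-B"`, in the order produced by [pair_labels()].
#' @export
build_pair_adjacency <- function(adjacency) {
  stopifnot(inherits(adjacency, "adjacency"))
  n <- length(adjacency$labels)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  idx <- stats::setNames(seq_len(nrow(pairs)),
                         key(pairs[, 1], pairs[, 2]))
  nb <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    cand <- c(
      vapply(adjacency$neighbors[[j]][adjacency$neighbors[[j]] != i],
             function(k) idx[[key(i, k)]], integer(1)),
      vapply(adjacency$neighbors[[i]][adjacency$neighbors[[i]] != j],
             function(k) idx[[key(j, k)]], integer(1)))
    nb[[p]] <- sort(unique(cand))
  }
  structure(list(labels = pair_labels(adjacency$labels),
                 neighbors = nb, pairs = pairs),
            class = "adjacency")
}

#' Labels for all unordered channel pairs
#' @param labels channel labels.
#' @return Character vector `"A-B"` over all pairs `i < j`.
#' @export
pair_labels <- function(labels) {
  n <- length(labels)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  paste(labels[pairs[, 1]], labels[pairs[, 2]], sep = "-")
}

# -- internal geometry --------------------------------------------------

# voxel layout: channel-like dimension first, then 1 or 2 grid dimensions;
# voxel id = ch + n_ch * (i - 1)  [1D grid]
#           ch + n_ch * ((i - 1) + n1 * (j - 1))  [2D grid]
voxel_neighbors <- function(v, n_ch, grid, chan_nb) {
  ch <- (v - 1L) %% n_ch + 1L
  rest <- (v - 1L) %/% n_ch
  if (length(grid) == 1L) {
    i <- rest + 1L
    out <- c(if (i > 1L) v - n_ch, if (i < grid[1]) v + n_ch,
             (v - ch) + chan_nb[[ch]])
  } else {
    i <- rest %% grid[1] + 1L
    j <- rest %/% grid[1] + 1L
    out <- c(if (i > 1L) v - n_ch, if (i < grid[1]) v + n_ch,
             if (j > 1L) v - n_ch * grid[1],
             if (j < grid[2]) v + n_ch * grid[1],
             (v - ch) + chan_nb[[ch]])
  }
  out
}

# connected components of same-sign supra-threshold voxels; returns list
# of integer vectors (voxel ids)
find_clusters <- function(supra, signs, n_ch, grid, chan_nb) {
  comp <- list()
  in_set <- logical(n_ch * prod(grid))
  in_set[supra] <- TRUE
  seen <- logical(length(in_set))
  queue <- integer(length(supra))
  for (v0 in supra) {
    if (seen[v0]) next
    queue[1L] <- v0
    head <- 1L
    tail <- 1L
    seen[v0] <- TRUE
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      nbs <- voxel_neighbors(v, n_ch, grid, chan_nb)
      nbs <- nbs[in_set[nbs] & !seen[nbs] & signs[nbs] == signs[v]]
      if (length(nbs)) {
        seen[nbs] <- TRUE
        queue[tail + seq_along(nbs)] <- nbs
        tail <- tail + length(nbs)
      }
    }
    comp[[length(comp) + 1L]] <- queue[seq_len(tail)]
  }
  comp
}

# independent-samples pooled-variance t for all voxels and all label
# assignments in `amat` (logical matrix: assignments x subjects, TRUE = A)
perm_tstats <- function(x, amat, nA, nB) {
  n <- nA + nB
  sx <- colSums(x)
  sxx <- colSums(x^2)
  sA <- amat %*% x                    # assignments x voxels
  sAA <- amat %*% (x^2)
  sB <- rep(1, nrow(amat)) %o% sx - sA
  sBB <- rep(1, nrow(amat)) %o% sxx - sAA
  mA <- sA / nA
  mB <- sB / nB
  ssA <- sAA - nA * mA^2
  ssB <- sBB - nB * mB^2
  sp2 <- (ssA + ssB) / (n - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mA - mB) / se
  t[!is.finite(t)] <- 0
  t
}

max_cluster_mass <- function(tvec, t_crit, n_ch, grid, chan_nb) {
  supra <- which(abs(tvec) > t_crit)
  if (!length(supra)) return(0)
  signs <- sign(tvec)
  comp <- find_clusters(supra, signs, n_ch, grid, chan_nb)
  max(abs(vapply(comp, function(m) sum(tvec[m]), numeric(1))))
}

#' Independent-samples cluster-based permutation t-test
#'
#' Nonparametric family-wise-error-controlled comparison of two groups of
#' per-subject maps over an electrode x grid space. Per voxel, a pooled
#' two-sample t is computed; voxels with `|t|` above the two-tailed
#' critical value at `alpha_cluster` (df = nA + nB - 2) are clustered by
#' spatial adjacency (neighbouring channels at the same bin) and grid
#' 4-connectivity (adjacent bins on the same channel), separately by sign.
#' The cluster statistic is the mass (sum of member t values); group
#' labels are permuted `n_perm` times and each observed cluster's Monte
#' Carlo p is `(b + 1) / (n_perm + 1)` with `b` the number of permutations
#' whose maximum |mass| reaches the observed |mass|
#' (`ci_range = 1.96 * sqrt(p (1 - p) / n_perm)`). With
#' `permutations = "exhaustive"` all label partitions are enumerated and p
#' is the exact proportion (the observed labelling included).
#'
#' @param group_a,group_b numeric arrays `[subjects, channels, ...grid]`
#'   on a common voxel grid (1 or 2 grid dimensions).
#' @param adjacency channel (or channel-pair) [build_adjacency()] graph
#'   whose nodes match dimension 2 of the data.
#' @param alpha_cluster voxel-level two-tailed threshold (default 0.001).
#' @param n_perm number of random permutations (default 1000).
#' @param seed RNG seed for the permutation stream.
#' @param permutations `"monte-carlo"` or `"exhaustive"`.
#' @return An object of class `cluster_result`: `clusters` (list with
#'   `voxels` matrix, `sign`, `mass`, `p`, `ci_range`), `tmap`,
#'   `null_max_mass`, `t_crit`, `df`, `n_perm`, `seed`, `method`.
#' @export
cluster_test <- function(group_a, group_b, adjacency,
                         alpha_cluster = 0.001, n_perm = 1000,
                         seed = 1, permutations = c("monte-carlo",
                                                    "exhaustive")) {
  permutations <- match.arg(permutations)
  da <- dim(group_a); db <- dim(group_b)
  if (is.null(da) || is.null(db) || length(da) != length(db) ||
      any(da[-1] != db[-1]))
    stop("groups must be arrays with a common channel/grid shape")
  nA <- da[1]; nB <- db[1]
  if (nA < 2L || nB < 2L) stop("each group needs at least 2 subjects")
  n_ch <- da[2]
  grid <- da[-(1:2)]
  if (length(grid) < 1L || length(grid) > 2L)
    stop("data must have 1 or 2 grid dimensions after the channel axis")
  if (length(adjacency$neighbors) != n_ch)
    stop("adjacency nodes must match the channel dimension")
  chan_nb <- adjacency$neighbors
  nv <- n_ch * prod(grid)
  x <- rbind(matrix(group_a, nrow = nA), matrix(group_b, nrow = nB))
  if (anyNA(x)) stop("cluster_test input contains missing values")
  n <- nA + nB
  df <- n - 2
  t_crit <- stats::qt(1 - alpha_cluster / 2, df)

  obs <- perm_tstats(x, matrix(c(rep(TRUE, nA), rep(FALSE, nB)), 1), nA, nB)
  tvec <- as.vector(obs)
  supra <- which(abs(tvec) > t_crit)
  clusters <- list()
  if (length(supra)) {
    comp <- find_clusters(supra, sign(tvec), n_ch, grid, chan_nb)
    clusters <- lapply(comp, function(m) {
      list(voxels = voxel_coords(m, n_ch, grid), ids = m,
           sign = sign(sum(tvec[m])), mass = sum(tvec[m]))
    })
  }

  if (permutations == "exhaustive") {
    combs <- utils::combn(n, nA)
    if (ncol(combs) > 20000)
      stop("too many partitions for exhaustive enumeration; ",
           "use Monte Carlo permutations")
    amat <- matrix(FALSE, ncol(combs), n)
    amat[cbind(rep(seq_len(ncol(combs)), each = nA), as.vector(combs))] <- TRUE
    n_used <- ncol(combs)
  } else {
    # use a private RNG stream for the permutations; the caller's
    # stream is left untouched
    if (exists(".Random.seed", envir = .GlobalEnv)) {
      old_seed <- get(".Random.seed", envir = .GlobalEnv)
      on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv),
              add = TRUE)
    }
    set.seed(seed)
    amat <- t(vapply(seq_len(n_perm),
                     function(i) seq_len(n) %in% sample.int(n, nA),
                     logical(n)))
    n_used <- n_perm
  }
  tperm <- perm_tstats(x, amat, nA, nB)
  null_max <- vapply(seq_len(n_used), function(i)
    max_cluster_mass(tperm[i, ], t_crit, n_ch, grid, chan_nb),
    numeric(1))

  for (k in seq_along(clusters)) {
    b <- sum(null_max >= abs(clusters[[k]]$mass) - 1e-12)
    if (permutations == "exhaustive") {
      p <- b / n_used
      ci <- 0
    } else {
      p <- (b + 1) / (n_used + 1)
      ci <- 1.96 * sqrt(p * (1 - p) / n_used)
    }
    clusters[[k]]$p <- p
    clusters[[k]]$ci_range <- ci
  }
  ord <- order(vapply(clusters, function(cl) -abs(cl$mass), numeric(1)))
  structure(list(clusters = clusters[ord],
                 tmap = array(tvec, dim = c(n_ch, grid)),
                 null_max_mass = null_max, t_crit = t_crit, df = df,
                 alpha_cluster = alpha_cluster, n_perm = n_used,
                 seed = if (permutations == "monte-carlo") seed else NA,
                 method = permutations, n_a = nA, n_b = nB,
                 labels = adjacency$labels),
            class = "cluster_result")
}

voxel_coords <- function(v, n_ch, grid) {
  ch <- (v - 1L) %% n_ch + 1L
  rest <- (v - 1L) %/% n_ch
  if (length(grid) == 1L) {
    cbind(channel = ch, bin = rest + 1L)
  } else {
    cbind(channel = ch, t1 = rest %% grid[1] + 1L,
          t2 = rest %/% grid[1] + 1L)
  }
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result (%s, %d permutations, alpha_cluster = %g)\n",
              x$method, x$n_perm, x$alpha_cluster))
  if (!length(x$clusters)) {
    cat("  no supra-threshold clusters\n")
    return(invisible(x))
  }
  show <- which(vapply(x$clusters, `[[`, 1, "p") < 0.05)
  if (!length(show)) show <- 1L
  hidden <- length(x$clusters) - length(show)
  for (k in show) {
    cl <- x$clusters[[k]]
    chans <- unique(cl$voxels[, 1])
    labs <- if (!is.null(x$labels))
      paste(x$labels[chans], collapse = ", ") else
        paste(chans, collapse = ", ")
    cat(sprintf("  cluster %d: sign %+d, %d voxels, mass %.2f, p = %.4g, ci-range = %.4g\n    channels: %s\n",
                k, cl$sign, nrow(cl$voxels), cl$mass, cl$p, cl$ci_range,
                labs))
  }
  if (hidden > 0)
    cat(sprintf("  ... %d further cluster(s) with p >= 0.05\n", hidden))
  invisible(x)
}

#' Exhaustive-permutation oracle for the cluster test
#'
#' Enumerates every assignment of subjects to groups (at most 20,000
#' partitions) and reports exact cluster p values: the proportion of
#' partitions, the observed labelling included, whose maximum |mass|
#' reaches the observed cluster's |mass|.
#'
#' @inheritParams cluster_test
#' @return A `cluster_result` with `method = "exhaustive"`.
#' @export
exhaustive_null <- function(group_a, group_b, adjacency,
                            alpha_cluster = 0.001) {
  cluster_test(group_a, group_b, adjacency,
               alpha_cluster = alpha_cluster,
               permutations = "exhaustive")
}

#' Per-subject mean of underlying condition values over a cluster
#'
#' Averages the (non-contrast) condition values over a cluster's voxels,
#' per subject and condition; the standard input to follow-up tests and
#' brain-behavior correlations.
#'
#' @param maps a [build_rdm_set()] `similarity_maps` object, or a
#'   `coherence_stack`, or a plain array `[subject, condition, channels,
#'   ...grid]`.
#' @param cluster one element of a `cluster_result`'s `clusters` list (or
#'   the `cluster_result` itself, in which case the first cluster is
#'   used).
#' @param conditions condition indices or (for `similarity_maps` /
#'   `coherence_stack`) condition key names; default all.
#' @return Data frame: `subject`, `group` (if known), one column per
#'   condition.
#' @export
extract_cluster_means <- function(maps, cluster, conditions = NULL) {
  if (inherits(cluster, "cluster_result")) {
    if (!length(cluster$clusters)) stop("cluster result is empty")
    cluster <- cluster$clusters[[1]]
  }
  if (inherits(maps, "similarity_maps")) {
    arr <- maps$z
    keys <- condition_key(maps$conditions)
    subjects <- maps$subjects
    groups <- maps$groups
  } else if (inherits(maps, "coherence_stack")) {
    arr <- maps$imcoh
    keys <- maps$condition_keys
    subjects <- maps$subjects
    groups <- maps$groups
  } else {
    arr <- maps
    keys <- paste0("cond", seq_len(dim(arr)[2]))
    subjects <- seq_len(dim(arr)[1])
    groups <- NULL
  }
  if (is.null(conditions)) conditions <- keys
  ci <- if (is.character(conditions)) match(conditions, keys) else conditions
  if (anyNA(ci)) stop("condition not found: ",
                      paste(conditions[is.na(ci)], collapse = ", "))
  vox <- cluster$voxels
  out <- data.frame(subject = subjects)
  if (!is.null(groups)) out$group <- groups
  d <- dim(arr)
  nd <- length(d)
  if (ncol(vox) != nd - 2L)
    stop("cluster voxel coordinates do not match the map dimensions")
  for (k in seq_along(ci)) {
    vals <- vapply(seq_len(d[1]), function(si) {
      idx <- cbind(si, ci[k], vox[, 1], vox[, 2],
                   if (nd == 5L) vox[, 3])
      mean(arr[idx], na.rm = TRUE)
    }, numeric(1))
    out[[keys[ci[k]]]] <- vals
  }
  out
}
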