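#' Uncentered correlation distance
#'
#' Cosine-form correlation distance without mean subtraction:
#' `d = 1 - sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))`, in `[0, 2]`.
#' This is the "uncentered correlation" metric of Cluster 3.0. Missing
#' values are handled pairwise-complete.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_shared Minimum pairwise-complete positions; fewer gives `NA`.
#' @return Distance scalar in `[0, 2]`, or error for a zero-norm vector.
#' @export
#' @examples
#' uncentered_distance(c(1, 2), c(2, 4))   # 0: scale invariant
#' uncentered_distance(c(1, 0), c(0, 1))   # 1: orthogonal
#' uncentered_distance(c(1, 2), c(-1, -2)) # 2: antipodal
uncentered_distance <- function(x, y, min_shared = 3) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_shared && sum(ok) < length(x)) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) abort("uncentered distance undefined for zero-norm vector")
  1 - sum(x * y) / (nx * ny)
}

# Full pairwise distance matrix over rows of m.
uncentered_dist_matrix <- function(m, min_shared = 3) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (!anyNA(m)) {
    norms <- sqrt(rowSums(m^2))
    if (any(norms == 0)) {
      bad <- rownames(m)[norms == 0]
      d[norms == 0, ] <- NA; d[, norms == 0] <- NA
      ok <- norms > 0
      g <- (m[ok, , drop = FALSE] %*% t(m[ok, , drop = FALSE])) /
        outer(norms[ok], norms[ok])
      d[ok, ok] <- 1 - g
    } else {
      d <- 1 - (m %*% t(m)) / outer(norms, norms)
    }
  } else {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j > i) {
          d[i, j] <- d[j, i] <- tryCatch(
            uncentered_distance(m[i, ], m[j, ], min_shared),
            error = function(e) NA_real_
          )
        }
      }
    }
  }
  diag(d) <- 0
  d
}

#' Hierarchical clustering with uncentered correlation and complete linkage
#'
#' Two-way-ready agglomerative clustering: items (features or samples) are
#' merged by complete ("full") linkage on the uncentered correlation
#' distance, the combination used by Cluster 3.0 for this kind of binding
#' data. Items with undefined distances (zero norm, or too few shared
#' observations with every partner) are excluded and reported.
#'
#' @param mat Wide binding tibble (feature column + sample columns).
#' @param axis `"features"` (cluster rows) or `"samples"` (cluster columns).
#' @param min_shared Pairwise-complete minimum for the distance.
#' @return An object of class `sh2_tree`: the `stats::hclust` merge tree
#'   plus `axis`, `distance`, `linkage` and `dropped` item ids.
#' @export
hcluster <- function(mat, axis = c("features", "samples"), min_shared = 3) {
  axis <- match.arg(axis)
  m <- binding_as_matrix(mat)
  if (axis == "samples") m <- t(m)
  if (nrow(m) < 2) abort("need at least 2 items to cluster")
  d <- uncentered_dist_matrix(m, min_shared)
  usable <- rowSums(is.na(d)) < (nrow(d) - 1)
  dropped <- rownames(d)[!usable]
  d <- d[usable, usable, drop = FALSE]
  if (nrow(d) < 2) abort("fewer than 2 items with defined distances")
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  structure(list(
    hclust = hc, axis = axis, distance = "uncentered_correlation",
    linkage = "complete", dropped = dropped
  ), class = "sh2_tree")
}

#' @export
print.sh2_tree <- function(x, ...) {
  cat("sh2_tree:", length(x$hclust$labels), "leaves on axis", x$axis,
      "|", x$distance, "/", x$linkage, "linkage\n")
  if (length(x$dropped)) {
    cat("dropped (undefined distance):", paste(x$dropped, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Cut a linkage tree into flat clusters
#'
#' @param tree An `sh2_tree` from [hcluster()].
#' @param k Number of clusters (exactly `k` groups), or
#' @param h Height: all merges above `h` are undone.
#' @return Tibble `item`, `cluster` covering every leaf.
#' @export
cut_tree <- function(tree, k = NULL, h = NULL) {
  stopifnot(inherits(tree, "sh2_tree"), xor(is.null(k), is.null(h)))
  cl <- if (!is.null(k)) stats::cutree(tree$hclust, k = k)
  else stats::cutree(tree$hclust, h = h)
  tibble(item = names(cl), cluster = unname(cl))
}

#' Permutation test for label enrichment in a cluster
#'
#' Tests whether a fixed cluster of samples contains surprisingly many
#' positively-labelled samples. The label vector is permuted over all
#' samples while the cluster membership is held fixed; the permutation
#' p-value uses add-one smoothing,
#' `p = (1 + #\{perm >= observed\}) / (1 + n_perm)`. The closed-form
#' hypergeometric upper-tail probability is reported alongside.
#'
#' @param members Character or logical vector identifying the cluster's
#'   samples (subset of `names(labels)` or a logical over samples).
#' @param labels Logical (or 0/1) label per sample, named when `members`
#'   is character.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @return An `enrichment_result`: cluster size `k`, population `N`,
#'   labelled `K`, observed in-cluster `x`, `p_perm`, `p_exact`, `n_perm`,
#'   `seed`.
#' @export
#' @examples
#' labels <- stats::setNames(rep(c(TRUE, FALSE), c(9, 13)), paste0("L", 1:22))
#' cluster_enrichment(paste0("L", 1:6), labels, n_perm = 1000, seed = 1)
cluster_enrichment <- function(members, labels, n_perm = 100000, seed = 1) {
  stopifnot(n_perm >= 1)
  lab <- as.logical(labels)
  N <- length(lab)
  if (is.character(members)) {
    if (is.null(names(labels))) abort("labels must be named for character members")
    if (!all(members %in% names(labels))) abort("members outside the sample set")
    in_cluster <- names(labels) %in% members
  } else {
    in_cluster <- as.logical(members)
    stopifnot(length(in_cluster) == N)
  }
  k <- sum(in_cluster)
  if (k == 0) abort("empty cluster")
  K <- sum(lab)
  x <- sum(lab & in_cluster)

  with_seed(seed, {
    # draw n_perm permutations of the label vector; count labelled samples
    # landing in the fixed cluster
    counts <- vapply(seq_len(n_perm), function(i) {
      sum(in_cluster[sample.int(N)] & lab)
    }, numeric(1))
    p_perm <- (1 + sum(counts >= x)) / (1 + n_perm)
  })
  p_exact <- stats::phyper(x - 1, K, N - K, k, lower.tail = FALSE)
  structure(list(
    k = k, N = N, K = K, x = x, p_perm = p_perm, p_exact = p_exact,
    n_perm = n_perm, seed = seed
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Cluster enrichment: %d/%d labelled in cluster of %d (N=%d, K=%d)\n",
    x$x, x$k, x$k, x$N, x$K))
  cat(sprintf("  permutation p = %.4g (n_perm = %d), exact p = %.4g\n",
              x$p_perm, x$n_perm, x$p_exact))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.enrichment_result <- function(x, ...) {
  res <- x
  tibble(k = res$k, N = res$N, K = res$K, x = res$x, p_perm = res$p_perm,
         p_exact = res$p_exact, n_perm = res$n_perm, seed = res$seed)
}

#' Export a clustered matrix in Cluster 3.0 / Java TreeView format
#'
#' Writes the CDT file (matrix reordered to the trees' leaf orders, with
#' GID/AID columns) and the GTR/ATR node files. Node heights follow the
#' TreeView correlation convention: `1 - merge distance`.
#'
#' @param mat Wide binding tibble.
#' @param row_tree,col_tree `sh2_tree` objects for features and samples
#'   (either may be `NULL`).
#' @param basename Output path without extension; writes `basename.cdt`
#'   and, per tree, `basename.gtr` / `basename.atr`.
#' @return Invisibly, the paths written.
#' @export
export_cdt <- function(mat, row_tree = NULL, col_tree = NULL, basename) {
  m <- binding_as_matrix(mat)
  row_order <- if (!is.null(row_tree)) {
    row_tree$hclust$labels[row_tree$hclust$order]
  } else rownames(m)
  col_order <- if (!is.null(col_tree)) {
    col_tree$hclust$labels[col_tree$hclust$order]
  } else colnames(m)
  m <- m[row_order, col_order, drop = FALSE]

  gid <- paste0("GENE", seq_len(nrow(m)), "X")
  aid <- paste0("ARRY", seq_len(ncol(m)), "X")
  paths <- character(0)

  header <- c("GID", "UNIQID", "NAME", "GWEIGHT", colnames(m))
  lines <- paste(header, collapse = "\t")
  if (!is.null(col_tree)) {
    lines <- c(lines, paste(c("AID", "", "", "", aid), collapse = "\t"))
  }
  lines <- c(lines, paste(c("EWEIGHT", "", "", "",
                            rep("1", ncol(m))), collapse = "\t"))
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(gid[i], rownames(m)[i], rownames(m)[i], "1",
            format(m[i, ], trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  cdt_path <- paste0(basename, ".cdt")
  writeLines(c(lines, body), cdt_path)
  paths <- c(paths, cdt_path)

  write_tree_file <- function(tree, ids, prefix, ext) {
    hc <- tree$hclust
    n <- length(hc$labels)
    node_name <- function(j) {
      if (j < 0) ids[match(hc$labels[-j], hc$labels)]
      else paste0("NODE", j, "X")
    }
    id_of_leaf <- setNames(ids, hc$labels)
    rows <- vapply(seq_len(n - 1), function(i) {
      a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
      nm <- function(v) {
        if (v < 0) id_of_leaf[[hc$labels[-v]]] else paste0("NODE", v, "X")
      }
      paste(c(paste0("NODE", i, "X"), nm(a), nm(b),
              format(1 - hc$height[i], trim = TRUE)), collapse = "\t")
    }, character(1))
    path <- paste0(basename, ext)
    writeLines(rows, path)
    path
  }
  if (!is.null(row_tree)) {
    ids <- setNames(gid, rownames(m))[row_tree$hclust$labels]
    paths <- c(paths, write_tree_file(row_tree, unname(ids), "GENE", ".gtr"))
  }
  if (!is.null(col_tree)) {
    ids <- setNames(aid, colnames(m))[col_tree$hclust$labels]
    paths <- c(paths, write_tree_file(col_tree, unname(ids), "ARRY", ".atr"))
  }
  invisible(paths)
}

#' Read the matrix back out of an exported CDT file
#'
#' @param path Path to a `.cdt` file written by [export_cdt()].
#' @return Wide binding tibble (feature column `feature`).
#' @export
read_cdt <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t")[[1]]
  samples <- header[-(1:4)]
  body <- lines[grepl("^GENE[0-9]+X\t", lines)]
  parts <- strsplit(body, "\t")
  vals <- t(vapply(parts, function(p) as.numeric(p[-(1:4)]),
                   numeric(length(samples))))
  out <- tibble(feature = vapply(parts, `[[`, character(1), 2))
  dplyr::bind_cols(out, as_tibble(setNames(as.data.frame(vals), samples)))
}
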