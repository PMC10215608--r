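#' Genomic relationship matrix (GRM)
#'
#' Standardised-dosage GRM: `G = (1/m) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) /
#' (2 p_i (1 - p_i))` over sites i with allele frequency p estimated from
#' the panel. Missing dosages are mean-imputed per site; monomorphic sites
#' are excluded with a warning.
#'
#' @param panel A [genotype_panel()].
#' @return Symmetric samples-by-samples matrix with sample dimnames.
#' @export
compute_grm <- function(panel) {
  g <- panel$geno
  p <- rowMeans(g, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1 | is.na(p)
  if (any(mono)) {
    warning(sum(mono), " monomorphic site(s) excluded from GRM")
    g <- g[!mono, , drop = FALSE]
    p <- p[!mono]
  }
  m <- nrow(g)
  if (m == 0) stop("no polymorphic sites", call. = FALSE)
  mu <- 2 * p
  sdv <- sqrt(2 * p * (1 - p))
  z <- (g - mu) / sdv
  z[is.na(z)] <- 0 # mean imputation of missing dosages
  grm <- crossprod(z) / m
  dimnames(grm) <- list(panel$samples, panel$samples)
  grm
}

#' Principal components of a GRM
#'
#' Top-k eigenpairs of the (symmetric) GRM; sample coordinates are
#' eigenvectors scaled by the square root of their eigenvalues. The percent
#' of variance explained is reported two ways: `pve` over all non-negative
#' eigenvalues and `pve_topk` renormalised over the k retained components.
#'
#' @param grm Symmetric matrix from [compute_grm()].
#' @param k Number of components (<= number of samples).
#' @return Object of class `pca_result`: list with `coordinates` (tibble
#'   `sample`, `PC1`..`PCk`), `eigenvalues`, `pve`, `pve_topk` and
#'   `vectors` (the raw orthonormal eigenvectors).
#' @export
grm_pca <- function(grm, k = 10) {
  stopifnot(isSymmetric(unname(grm), tol = 1e-8))
  n <- nrow(grm)
  if (k > n) stop("k exceeds sample count", call. = FALSE)
  if (is.null(rownames(grm))) {
    rownames(grm) <- colnames(grm) <- sprintf("S%d", seq_len(n))
  }
  e <- eigen((grm + t(grm)) / 2, symmetric = TRUE)
  lam <- e$values
  pos_sum <- sum(pmax(lam, 0))
  lam_k <- lam[seq_len(k)]
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(lam_k, 0)), k, k)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(
    coordinates = dplyr::bind_cols(
      tibble::tibble(sample = rownames(grm)),
      tibble::as_tibble(coords)
    ),
    eigenvalues = lam_k,
    pve = 100 * lam_k / pos_sum,
    pve_topk = 100 * pmax(lam_k, 0) / sum(pmax(lam_k, 0)),
    vectors = e$vectors[, seq_len(k), drop = FALSE]
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", length(x$eigenvalues), "components;",
      "PVE:", paste0(sprintf("%.2f", x$pve[seq_len(min(3, length(x$pve)))]),
                     "%", collapse = ", "), "...\n")
  invisible(x)
}

#' Identity-by-state distance matrix
#'
#' `d(j, k) = 1 - (mean shared alleles per site) / 2` over sites where both
#' samples are called; shared alleles per site are `2 - |dosage_j -
#' dosage_k|`.
#'
#' @param panel A [genotype_panel()].
#' @return Symmetric distance matrix with sample dimnames, zero diagonal.
#' @export
ibs_distance <- function(panel) {
  g <- panel$geno
  n <- ncol(g)
  d <- matrix(0, n, n, dimnames = list(panel$samples, panel$samples))
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      ok <- !is.na(g[, j]) & !is.na(g[, k])
      if (!any(ok)) {
        stop("no jointly called sites for pair ", panel$samples[j], " / ",
             panel$samples[k], call. = FALSE)
      }
      ibs <- 2 - abs(g[ok, j] - g[ok, k])
      d[j, k] <- d[k, j] <- 1 - mean(ibs) / 2
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i, j) = (r - 2) d(i, j) - R_i - R_j` is joined (ties broken by the
#' lexicographically smallest pair of node labels, an internal node being
#' labelled by the smallest leaf beneath it), with branch lengths from the
#' standard split formula. Negative branch lengths are clamped to zero and
#' the deficit transferred to the sister branch so the output is a valid
#' ultrametric-free Newick tree.
#'
#' @param dist Symmetric distance matrix with labels as dimnames.
#' @return An `ape` `phylo` object (unrooted for >= 3 leaves).
#' @export
neighbor_joining <- function(dist) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  if (!isSymmetric(unname(dist), tol = 1e-10)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  labels <- rownames(dist)
  if (is.null(labels)) labels <- colnames(dist)
  if (is.null(labels)) stop("distance matrix needs labels", call. = FALSE)
  n <- nrow(dist)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)

  d <- unname(dist)
  # build with placeholder tip names (ape's parser mangles quoted labels);
  # the true labels are restored on the returned phylo object
  frag <- sprintf("mstip%d", seq_len(n))
  key <- labels

  while (nrow(d) > 3) {
    r <- nrow(d)
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_key <- apply(cand, 1, function(ij) {
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r")
    })
    best <- cand[order(pair_key)[1], ]
    i <- best[1]; j <- best[2]

    bi <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    lens <- clamp_branch_pair(bi, bj)
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], lens[1],
                        frag[j], lens[2])
    new_key <- min(key[i], key[j])
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
  }

  # final three-way join around the last internal node
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  ord <- order(key)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[ord[1]], b[ord[1]], frag[ord[2]], b[ord[2]],
                 frag[ord[3]], b[ord[3]])
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labels[as.integer(sub("^mstip", "", tree$tip.label))]
  tree
}

# clamp a negative branch in a freshly joined pair, moving the deficit to
# the sister so the path length through the new node is preserved
clamp_branch_pair <- function(bi, bj) {
  if (bi < 0) {
    bj <- bj + bi
    bi <- 0
  }
  if (bj < 0) {
    bi <- bi + bj
    bj <- 0
  }
  c(max(bi, 0), max(bj, 0))
}

quote_newick_label <- function(x) {
  if (grepl("[][ \t():;,']", x)) {
    paste0("'", gsub("'", "''", x), "'")
  } else {
    x
  }
}

#' Serialise a tree to Newick text
#'
#' Standard Newick with branch lengths; labels containing spaces or Newick
#' metacharacters are single-quoted. `write_newick(read_newick(x))` is
#' idempotent.
#'
#' @param tree An `ape` `phylo` object.
#' @param path Optional file to write to.
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  render <- function(node) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) {
      return(quote_newick_label(tree$tip.label[node]))
    }
    inner <- vapply(kids, function(e) {
      child <- tree$edge[e, 2]
      len <- if (is.null(tree$edge.length)) "" else
        sprintf(":%.12g", tree$edge.length[e])
      paste0(render(child), len)
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  out <- paste0(render(root), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Parse Newick text
#'
#' Single-quoted labels (used for names containing spaces or Newick
#' metacharacters) are preserved verbatim.
#'
#' @param text Newick string or path to a file containing one.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(text) {
  if (file.exists(text)) text <- paste(readLines(text), collapse = "")
  # shelter quoted labels from ape's parser
  m <- gregexpr("'(?:[^']|'')*'", text)[[1]]
  quoted <- character(0)
  if (m[1] != -1) {
    quoted <- regmatches(text, gregexpr("'(?:[^']|'')*'", text))[[1]]
    for (i in seq_along(quoted)) {
      text <- sub(quoted[i], sprintf("msquot%d", i), text, fixed = TRUE)
    }
  }
  tree <- ape::read.tree(text = text)
  if (length(quoted) > 0) {
    idx <- grepl("^msquot\\d+$", tree$tip.label)
    orig <- gsub("''", "'",
                 sub("^'(.*)'$", "\\1",
                     quoted[as.integer(sub("^msquot", "",
                                           tree$tip.label[idx]))]))
    tree$tip.label[idx] <- orig
  }
  tree
}

#' Mean silhouette width of a two-group split along coordinates
#'
#' Euclidean silhouette: for each sample, `(b - a) / max(a, b)` with `a`
#' the mean distance to its own group and `b` to the other group; returns
#' the mean over samples. Values near 1 indicate clean separation.
#'
#' @param coords Numeric vector or matrix of coordinates (rows = samples).
#' @param groups Group label per sample (exactly two distinct values).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
group_silhouette <- function(coords, groups) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(groups),
            dplyr::n_distinct(groups) == 2)
  d <- as.matrix(stats::dist(coords))
  s <- vapply(seq_len(nrow(coords)), function(i) {
    own <- groups == groups[i]
    own[i] <- FALSE
    a <- mean(d[i, own])
    b <- mean(d[i, !own & seq_along(groups) != i])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Do the two groups form monophyletic clades on an unrooted tree?
#'
#' True when some single edge of the tree separates all `"high"` samples
#' from all `"low"` samples (the bipartition test appropriate for unrooted
#' trees).
#'
#' @param tree An `ape` `phylo` object whose tip labels are sample ids.
#' @param groups Named character vector mapping tip labels to groups.
#' @return Logical.
#' @export
groups_monophyletic <- function(tree, groups) {
  g <- groups[tree$tip.label]
  target <- sort(tree$tip.label[g == "high"])
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  all_tips <- sort(tree$tip.label)
  for (p in parts) {
    clade <- sort(labs[p])
    if (identical(clade, target) ||
        identical(sort(setdiff(all_tips, clade)), target)) {
      return(TRUE)
    }
  }
  FALSE
}
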