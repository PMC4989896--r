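## Tree construction and comparison.
##
## UPGMA is implemented directly so that the merge heights (linkage values)
## are available for dendrogram diagnostics and the tie-break rule is fixed;
## neighbor joining and Newick serialization are delegated to 'ape'.
## Robinson-Foulds is an independent bipartition implementation (tested
## against phangorn's).

.as_dist_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (anyNA(m)) stop("distance matrix contains NaN/NA entries")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix is not symmetric")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("S", seq_len(nrow(m)))
  m
}

#' UPGMA clustering of a dissimilarity matrix
#'
#' Agglomerative clustering with arithmetic-mean (average) linkage.  The
#' result is an ultrametric rooted dendrogram; each internal node's height
#' is the linkage dissimilarity at which its two subtrees merge, and the
#' corresponding tree node sits at half that value so that leaf-to-leaf
#' path lengths reproduce the (ultrametric) input.  Ties are broken by the
#' lowest `(row, column)` index pair, making the output reproducible.
#'
#' @param m symmetric non-negative matrix with zero diagonal (a
#'   `dissimilarity_matrix` or plain matrix).
#' @return an object of class `c("kmerq_upgma", "hclust")`; convert with
#'   `ape::as.phylo()` for Newick export (branch lengths are half-heights).
#' @examples
#' m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- upgma(m)
#' ape::write.tree(ape::as.phylo(tr))  # ((A:1,B:1):1,C:2);
#' @export
upgma <- function(m) {
  m <- .as_dist_matrix(m)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 samples")
  labs <- rownames(m)
  D <- m
  active <- rep(TRUE, n)
  cl_id <- -seq_len(n)          # hclust codes: negative = singleton
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    idx <- which(active)
    best <- c(NA_integer_, NA_integer_); bestv <- Inf
    for (a in seq_along(idx)) {
      i <- idx[a]
      if (a == length(idx)) break
      js <- idx[(a + 1L):length(idx)]
      v <- D[i, js]
      jmin <- which(v < bestv)
      if (length(jmin) > 0L) {       # strict '<': earlier (i,j) wins ties
        jbest <- jmin[which.min(v[jmin])]
        ## among equal minima within this row, keep the lowest column
        jbest <- jmin[v[jmin] == min(v[jmin])][1]
        bestv <- v[jbest]
        best <- c(i, js[jbest])
      }
    }
    i <- best[1]; j <- best[2]
    merge[s, ] <- c(cl_id[i], cl_id[j])
    height[s] <- bestv
    ## average-linkage update, new cluster stored in slot i
    others <- setdiff(idx, c(i, j))
    if (length(others) > 0L) {
      newd <- (sizes[i] * D[i, others] + sizes[j] * D[j, others]) /
        (sizes[i] + sizes[j])
      D[i, others] <- newd
      D[others, i] <- newd
    }
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    cl_id[i] <- s
  }
  ord <- integer(0)
  walk <- function(code) {
    if (code < 0L) ord <<- c(ord, -code)
    else { walk(merge[code, 1]); walk(merge[code, 2]) }
  }
  walk(n - 1L)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labs, method = "average",
                 call = match.call(), dist.method = "kmerq"),
            class = c("kmerq_upgma", "hclust"))
}

#' Neighbor-joining tree from a dissimilarity matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`).  Negative branch lengths,
#' which NJ can produce on non-additive input, are set to zero with the
#' deficit transferred to the sibling branch so that paths through the
#' parent node are preserved; any remainder is clamped at zero.
#'
#' @param m symmetric dissimilarity matrix, at least 3 samples.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(m) {
  m <- .as_dist_matrix(m)
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 samples")
  tr <- ape::nj(m)
  for (pass in 1:10) {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1]
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sib) > 0L)
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

.as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (inherits(tree, "hclust")) return(ape::as.phylo(tree))
  stop("expected a 'phylo' or 'hclust'/'kmerq_upgma' tree")
}

## canonical non-trivial bipartitions of an unrooted tree, as label-set keys
.tree_splits <- function(tr) {
  tr <- ape::unroot(.as_phylo_tree(tr))
  tips <- tr$tip.label
  n <- length(tips)
  ntot <- n + tr$Nnode
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  below <- vector("list", ntot)
  fill <- function(v) {
    if (v <= n) return(tips[v])
    res <- unlist(lapply(kids[[as.character(v)]], fill))
    below[[v]] <<- res
    res
  }
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  fill(root)
  ref <- sort(tips)[1]
  keys <- character(0)
  for (v in setdiff(unique(tr$edge[, 2]), seq_len(n))) {
    s <- below[[v]]
    if (length(s) <= 1L || length(s) >= n - 1L) next
    if (ref %in% s) s <- setdiff(tips, s)
    keys <- c(keys, paste(sort(s), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds symmetric distance between two trees
#'
#' Both trees are treated as unrooted; the distance is the number of
#' non-trivial bipartitions present in exactly one of the two trees.  It is
#' 0 if and only if the unrooted topologies are identical, and at most
#' `2(n-3)` for binary trees on `n` leaves.
#'
#' @param t1,t2 trees (`phylo` or `hclust`/`kmerq_upgma`) on the same leaf
#'   label set.
#' @return integer distance.
#' @export
robinson_foulds <- function(t1, t2) {
  p1 <- .as_phylo_tree(t1); p2 <- .as_phylo_tree(t2)
  l1 <- sort(p1$tip.label); l2 <- sort(p2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    stop("trees have different leaf sets; only in first: {",
         paste(only1, collapse = ","), "}, only in second: {",
         paste(only2, collapse = ","), "}")
  }
  s1 <- .tree_splits(p1); s2 <- .tree_splits(p2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

.check_partition <- function(tree, partition, two_class = TRUE) {
  labs <- if (inherits(tree, "hclust")) tree$labels else tree$tip.label
  if (is.null(names(partition))) stop("partition must be named by leaf label")
  if (!setequal(names(partition), labs))
    stop("partition labels do not match tree leaves")
  cls <- unique(partition)
  if (two_class && length(cls) != 2L)
    stop("statistic is defined for exactly 2 classes, got ", length(cls))
  partition[labs]
}

## leaf index sets for each merge row of an hclust object
.merge_leafsets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  getset <- function(code) if (code < 0L) -code else sets[[code]]
  for (s in seq_len(n - 1L))
    sets[[s]] <- c(getset(hc$merge[s, 1]), getset(hc$merge[s, 2]))
  sets
}

#' Height of the node separating two classes in a dendrogram
#'
#' Finds the internal node whose merge joins exactly the two classes of the
#' reference partition (one class per subtree) and returns its merge
#' dissimilarity — the linkage value at which the two classes join.  The
#' higher this node relative to the merges below it, the better the measure
#' discriminates the classes.  If no node induces the partition the
#' clustering has failed and `NA` is returned.
#'
#' @param tree an `hclust`/`kmerq_upgma` dendrogram.
#' @param partition named vector mapping each leaf label to one of exactly
#'   two class labels.
#' @return the merge height, or `NA_real_` on classification failure.
#' @export
discriminating_node_height <- function(tree, partition) {
  stopifnot(inherits(tree, "hclust"))
  part <- .check_partition(tree, partition, two_class = TRUE)
  cls <- unique(part)
  setA <- which(part == cls[1])
  sets <- .merge_leafsets(tree)
  n <- length(tree$labels)
  for (s in seq_len(n - 1L)) {
    left <- if (tree$merge[s, 1] < 0L) -tree$merge[s, 1] else sets[[tree$merge[s, 1]]]
    right <- if (tree$merge[s, 2] < 0L) -tree$merge[s, 2] else sets[[tree$merge[s, 2]]]
    if ((setequal(left, setA) && setequal(right, setdiff(seq_len(n), setA))) ||
        (setequal(right, setA) && setequal(left, setdiff(seq_len(n), setA))))
      return(tree$height[s])
  }
  NA_real_
}

#' Fraction of leaves assigned to their true class by a dendrogram cut
#'
#' Cuts the dendrogram into as many clusters as the partition has classes
#' and returns the fraction of leaves whose cluster matches their class
#' under the best cluster-to-class assignment.
#'
#' @param tree an `hclust`/`kmerq_upgma` dendrogram.
#' @param partition named vector mapping leaf labels to class labels.
#' @return fraction in `[0, 1]`.
#' @export
clustering_accuracy <- function(tree, partition) {
  stopifnot(inherits(tree, "hclust"))
  part <- .check_partition(tree, partition, two_class = FALSE)
  cls <- unique(part)
  c_n <- length(cls)
  if (c_n == 1L) return(1.0)
  cut <- stats::cutree(tree, k = c_n)
  perms <- .permutations(c_n)
  best <- 0
  for (p in seq_len(nrow(perms))) {
    assigned <- cls[perms[p, cut]]
    best <- max(best, mean(assigned == part))
  }
  best
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' Newick import and export
#'
#' Thin wrappers around `ape`'s Newick reader/writer that accept this
#' package's dendrogram objects and give positioned parse errors.
#'
#' @param x a tree (`phylo` or `hclust`/`kmerq_upgma`).
#' @param path file path; for `read_newick` a path or a literal Newick
#'   string.
#' @return `write_newick` returns `path` invisibly; `read_newick` a
#'   `phylo` tree.
#' @export
write_newick <- function(x, path) {
  tr <- .as_phylo_tree(x)
  n <- length(tr$tip.label)
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  quote_label <- function(l) {
    if (grepl("[^A-Za-z0-9._-]", l))
      paste0("'", gsub("'", "''", l), "'")
    else l
  }
  fmt_len <- function(e) {
    if (is.null(tr$edge.length)) "" else sprintf(":%.10g", tr$edge.length[e])
  }
  rec <- function(node, edge_in) {
    body <- if (node <= n) {
      quote_label(tr$tip.label[node])
    } else {
      es <- kids[[as.character(node)]]
      paste0("(", paste(vapply(es, function(e) rec(tr$edge[e, 2], e),
                               character(1)), collapse = ","), ")")
    }
    if (is.na(edge_in)) body else paste0(body, fmt_len(edge_in))
  }
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  writeLines(paste0(rec(root, NA), ";"), path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- if (file.exists(path)) paste(readLines(path), collapse = "") else path
  if (!grepl(";", txt))
    stop("malformed Newick: no terminating ';' (at end of input)")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) {
    depth <- cumsum((utf8ToInt(txt) == utf8ToInt("(")) -
                      (utf8ToInt(txt) == utf8ToInt(")")))
    pos <- if (any(depth < 0)) which(depth < 0)[1] else nchar(txt)
    stop("malformed Newick near character ", pos)
  }
  ## ape keeps surrounding quotes in labels; strip them
  unquote <- function(l) {
    q <- grepl("^'.*'$", l)
    l[q] <- gsub("''", "'", substr(l[q], 2L, nchar(l[q]) - 1L))
    l
  }
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  tr
}
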