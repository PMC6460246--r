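#' p-distance matrix from a multiple alignment
#'
#' Pairwise deletion: for each pair of rows the distance is the proportion of
#' mismatching residues among columns where both rows carry a residue.
#'
#' @param x an [msa] with at least 3 rows.
#' @return A symmetric numeric matrix with zero diagonal, labelled by row id.
#' @export
p_distance_matrix <- function(x) {
  stopifnot(inherits(x, "msa"))
  if (x$n_rows < 3) stop("need at least 3 rows")
  m <- msa_matrix(x)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(x$id, x$id))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pij <- row_p_distance(m[i, ], m[j, ])
    if (is.na(pij))
      stop("rows '", x$id[i], "' and '", x$id[j],
           "' share no non-gap columns")
    d[i, j] <- d[j, i] <- pij
  }
  d
}

check_dist <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (any(d < 0)) stop("negative distances")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(!is.finite(d))) stop("non-finite distances")
  d
}

fmt_len <- function(x) sprintf("%.10g", x)

#' Neighbor-joining tree
#'
#' Saitou--Nei agglomeration with the standard Q criterion. Ties in Q are
#' broken by the lexicographically smallest label pair and negative branch
#' lengths are clamped to zero, so the output is reproducible across
#' platforms. The result is an unrooted binary tree of class `phylo` (ape).
#'
#' @param d labelled symmetric distance matrix with at least 3 taxa.
#' @return An ape `phylo` object.
#' @export
neighbor_joining <- function(d) {
  d <- check_dist(d)
  labels <- rownames(d)
  m <- nrow(d)
  if (m < 3) stop("need at least 3 taxa")
  # each active cluster carries a Newick fragment; tips enter as safe
  # placeholders so arbitrary labels survive the round trip
  orig <- labels
  frag <- paste0("t", seq_len(m))
  safe <- frag
  while (m > 3) {
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_lab <- t(apply(cand, 1, function(ij) sort(labels[ij])))
    pick <- order(pair_lab[, 1], pair_lab[, 2])[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    vi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    vi <- max(0, vi); vj <- max(0, vj)
    newfrag <- paste0("(", frag[i], ":", fmt_len(vi), ",",
                      frag[j], ":", fmt_len(vj), ")")
    dk <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    # the merged cluster inherits its smaller member's label for tie-breaking
    labels <- c(labels[keep], min(labels[c(i, j)]))
    rownames(d2) <- colnames(d2) <- labels
    frag <- c(frag[keep], newfrag)
    d <- d2
    m <- m - 1
  }
  v1 <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  v2 <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  v3 <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- paste0("(", frag[1], ":", fmt_len(v1), ",",
                frag[2], ":", fmt_len(v2), ",",
                frag[3], ":", fmt_len(v3), ");")
  tr <- ape::read.tree(text = nwk)
  tr$tip.label <- orig[match(tr$tip.label, safe)]
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Columns of the alignment are resampled with replacement `n_replicates`
#' times; each replicate alignment yields a p-distance NJ tree, and the
#' support of each internal edge of the original tree is the percentage of
#' replicates whose tree contains the same (unrooted) leaf bipartition.
#' Replicates in which some pair shares no sampled residue columns are
#' counted as containing no bipartitions.
#'
#' @param x an [msa].
#' @param n_replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @return The NJ tree (`phylo`) with `node.label` set to supports in
#'   `[0, 100]` (the root label is empty).
#' @export
bootstrap_support <- function(x, n_replicates = 1000, seed) {
  stopifnot(inherits(x, "msa"), n_replicates >= 1)
  if (missing(seed)) stop("seed is required for bootstrap resampling")
  base <- neighbor_joining(p_distance_matrix(x))
  set.seed(as.integer(seed))
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(x$n_columns, x$n_columns, replace = TRUE)
    mm <- msa_matrix(x)[, cols, drop = FALSE]
    rows <- apply(mm, 1, paste, collapse = "")
    tr <- tryCatch(neighbor_joining(p_distance_matrix(msa(x$id, rows))),
                   error = function(e) NULL)
    reps[[b]] <- tr
  }
  ok <- !vapply(reps, is.null, logical(1))
  counts <- rep(0, base$Nnode)
  if (any(ok)) {
    cl <- ape::prop.clades(base, reps[ok], rooted = FALSE)
    cl[is.na(cl)] <- 0
    counts <- cl
  }
  support <- 100 * counts / n_replicates
  base$node.label <- c("", sprintf("%g", support[-1]))
  attr(base, "support") <- support
  base
}

quote_label <- function(lab) {
  ifelse(grepl("[[:space:]]", lab), paste0("'", lab, "'"), lab)
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written to 6 decimals and internal-node labels
#' (bootstrap supports) are preserved; labels containing spaces are quoted.
#'
#' @param tree a `phylo` object.
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tr <- tree
  if (!is.null(tr$edge.length)) tr$edge.length <- round(tr$edge.length, 6)
  tr$tip.label <- quote_label(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- quote_label(tr$node.label)
  txt <- ape::write.tree(tr)
  # ape writes spaces as underscores; restore them inside quoted labels
  spaced <- unique(c(tree$tip.label, tree$node.label))
  spaced <- spaced[!is.null(spaced) & grepl("[[:space:]]", spaced)]
  for (lab in spaced)
    txt <- gsub(paste0("'", gsub(" ", "_", lab, fixed = TRUE), "'"),
                paste0("'", lab, "'"), txt, fixed = TRUE)
  if (is.null(path)) txt else { writeLines(txt, path); invisible(txt) }
}

#' Parse a Newick tree
#'
#' @param x a Newick string or a path to a Newick file.
#' @return A `phylo` object; quoted labels are unquoted.
#' @export
from_newick <- function(x) {
  txt <- if (file.exists(x) && !grepl("\\(", x)) paste(readLines(x), collapse = "") else x
  if (!grepl("\\(", txt)) stop("not a Newick string")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) stop("Newick parse error: unbalanced parentheses")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("Newick parse error")
  tr$tip.label <- gsub("^'|'$", "", tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- gsub("^'|'$", "", tr$node.label)
  tr
}

#' Outgroup-rooted clade membership
#'
#' The tree is rooted on the outgroup attachment edge and the candidate is
#' placed relative to the family clade. Under the default `"mrca"` rule the
#' candidate is `"inside"` when it descends from the most recent common
#' ancestor of the designated family members. The `"attachment"` rule
#' instead asks whether the smallest clade containing the family members
#' *and* the candidate is free of outgroup leaves; it tolerates candidates
#' attaching basally to a sparse anchor set, and presumes the outgroup set
#' represents every non-family clade (the published analysis used both the
#' 4-O- and 6-O-sulfatase families as outgroup in exactly this way). When
#' the outgroup is not monophyletic after rooting, a warning is issued and
#' the tree is rooted at the MRCA of the outgroup instead.
#'
#' @param tree a `phylo` object.
#' @param family_labels leaf labels of the known family members.
#' @param outgroup_labels leaf labels of the outgroup (disjoint from family).
#' @param candidate a single leaf label to classify.
#' @param rule `"mrca"` (default) or `"attachment"`.
#' @return `"inside"` or `"outside"`.
#' @export
clade_membership <- function(tree, family_labels, outgroup_labels, candidate,
                             rule = c("mrca", "attachment")) {
  rule <- match.arg(rule)
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing_ <- setdiff(c(family_labels, outgroup_labels, candidate), tips)
  if (length(missing_)) stop("not leaves of the tree: ",
                             paste(missing_, collapse = ", "))
  if (length(intersect(family_labels, outgroup_labels)))
    stop("family and outgroup labels must be disjoint")
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup_labels, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(rooted)) {
    warning("outgroup is not monophyletic; rooting at outgroup MRCA")
    node <- ape::getMRCA(tree, outgroup_labels)
    rooted <- tryCatch(ape::root(tree, node = node, resolve.root = TRUE),
                       error = function(e) tree)  # MRCA is already the root
  }
  anchor <- if (rule == "mrca") family_labels
            else unique(c(family_labels, candidate))
  if (length(anchor) == 1) {
    clade_tips <- anchor
  } else {
    mrca <- ape::getMRCA(rooted, anchor)
    clade_tips <- ape::extract.clade(rooted, mrca)$tip.label
  }
  inside <- if (rule == "mrca") candidate %in% clade_tips
            else !any(outgroup_labels %in% clade_tips)
  if (inside) "inside" else "outside"
}

#' Write a distance matrix in PHYLIP square format
#' @param d labelled symmetric distance matrix.
#' @param path output path.
#' @export
write_phylip_dist <- function(d, path) {
  d <- check_dist(d)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste0(sprintf("%-10s", rownames(d)[i]),
                      paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#' @param path input path.
#' @return A labelled symmetric matrix.
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  toks <- strsplit(trimws(lines[2:(n + 1)]), "[[:space:]]+")
  labs <- vapply(toks, `[[`, "", 1)
  d <- t(vapply(toks, function(tk) as.numeric(tk[-1]), numeric(n)))
  dimnames(d) <- list(labs, labs)
  check_dist(d)
}
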