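# Pigeonhole-principle phylogeny assembly.
#
# Two lineages whose cell fractions sum to more than 1 cannot occupy
# disjoint sets of tumor cells, so some cell carries both: the lineages are
# collinear on the tree, with the larger-fraction lineage ancestral. These
# forced nestings, plus collinear/exclusive constraints contributed by
# read-pair phasing, are honored by a greedy nesting of items in descending
# fraction order. Placements not forced by any constraint are kept under the
# most-recent common ancestor and flagged ambiguous, never guessed.

#' Pigeonhole constraints among lineage items
#'
#' For every pair of items whose cell fractions sum to more than 1, emits a
#' collinear constraint with the strictly-larger-fraction item ancestral
#' (ties yield collinearity with unresolved order, recorded with
#' \code{first = NA}).
#'
#' @param items data.frame with columns \code{label} and \code{fraction}
#'   (fractions of tumor cells, in (0, 1]).
#' @return data.frame of constraints: \code{a}, \code{b}, \code{relation}
#'   (\code{"collinear"}), \code{first} (label of the ancestral item, or NA
#'   for ties).
#' @examples
#' pigeonholeConstraints(data.frame(label = c("del13", "C"),
#'                                  fraction = c(0.68, 0.65)))
#' @export
pigeonholeConstraints <- function(items) {
  out <- NULL
  n <- nrow(items)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      fi <- items$fraction[i]; fj <- items$fraction[j]
      if (fi + fj > 1) {
        first <- if (fi > fj) items$label[i]
                 else if (fj > fi) items$label[j]
                 else NA_character_
        out <- rbind(out, data.frame(a = items$label[i], b = items$label[j],
                                     relation = "collinear", first = first,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    out <- data.frame(a = character(), b = character(),
                      relation = character(), first = character(),
                      stringsAsFactors = FALSE)
  out
}

.newNode <- function(label, fraction, nMutations = 0L, events = character(),
                     ambiguous = FALSE) {
  list(label = label, fraction = fraction, nMutations = as.integer(nMutations),
       events = events, ambiguous = ambiguous, children = list())
}

# path of labels from root to each node
.treePaths <- function(node, prefix = character()) {
  path <- c(prefix, node$label)
  out <- stats::setNames(list(path), node$label)
  for (ch in node$children) out <- c(out, .treePaths(ch, path))
  out
}

.findNode <- function(node, label) {
  if (node$label == label) return(node)
  for (ch in node$children) {
    hit <- .findNode(ch, label)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

.insertUnder <- function(node, parentLabel, child) {
  if (node$label == parentLabel) {
    node$children <- c(node$children, list(child))
    return(node)
  }
  node$children <- lapply(node$children, .insertUnder, parentLabel = parentLabel,
                          child = child)
  node
}

.checkSums <- function(node, eps) {
  if (length(node$children)) {
    s <- sum(vapply(node$children, function(ch) ch$fraction, numeric(1)))
    if (s > node$fraction + eps)
      stop(sprintf(
        "children of '%s' total %.3f, exceeding its fraction %.3f + eps",
        node$label, s, node$fraction))
    for (ch in node$children) .checkSums(ch, eps)
  }
  invisible(TRUE)
}

#' Assemble a clone tree from lineage fractions and constraints
#'
#' Items (mutation clusters and copy-number events, each with a fraction of
#' tumor cells) are nested greedily in descending fraction order. Pigeonhole
#' collinearity (fraction sums above 1) and any phasing-derived constraints
#' (\code{relation} \code{"collinear"} with a \code{first} label, or
#' \code{"exclusive"}) are honored exactly; an exclusive pair whose
#' fractions sum to more than 1 is a contradiction and raises an error
#' naming the pair. Items forced under no lineage stay children of the
#' most-recent common ancestor; if such an item could also nest inside a
#' sibling (no constraint resolves it), it is flagged ambiguous.
#'
#' @param items data.frame with columns \code{label}, \code{fraction} and
#'   optionally \code{nMutations} and \code{type} (\code{"cluster"} or
#'   \code{"cn_event"}).
#' @param constraints Optional extra constraints (same columns as
#'   \code{\link{pigeonholeConstraints}} output, plus relation
#'   \code{"exclusive"}).
#' @param epsilon Tolerance on children fraction sums (default 0.02).
#' @return A \code{\link{CloneTree}}.
#' @export
buildTree <- function(items, constraints = NULL, epsilon = 0.02) {
  stopifnot(all(c("label", "fraction") %in% names(items)))
  if (is.null(items$nMutations)) items$nMutations <- 0L
  if (is.null(items$type)) items$type <- "cluster"
  cons <- pigeonholeConstraints(items)
  if (!is.null(constraints) && nrow(constraints)) {
    if (is.null(constraints$first)) constraints$first <- NA_character_
    cons <- rbind(cons, constraints[, c("a", "b", "relation", "first")])
  }
  # contradiction: exclusive pair that pigeonhole forces together
  excl <- cons[cons$relation == "exclusive", , drop = FALSE]
  if (nrow(excl)) {
    fr <- stats::setNames(items$fraction, items$label)
    bad <- fr[excl$a] + fr[excl$b] > 1
    if (any(bad))
      stop("inconsistent constraints: exclusive pair(s) with fraction sum > 1: ",
           paste(sprintf("(%s, %s)", excl$a[bad], excl$b[bad]), collapse = ", "))
  }

  items <- items[order(items$fraction, decreasing = TRUE), , drop = FALSE]
  rootRow <- which(items$fraction >= 1 - 1e-9)
  if (length(rootRow)) {
    root <- .newNode(items$label[rootRow[1]], 1,
                     items$nMutations[rootRow[1]])
    rest <- items[-rootRow[1], , drop = FALSE]
  } else {
    root <- .newNode("MRCA", 1, 0L)
    rest <- items
  }

  collinear <- cons[cons$relation == "collinear" & !is.na(cons$first), ,
                    drop = FALSE]
  exclPairs <- excl
  for (i in seq_len(nrow(rest))) {
    lab <- rest$label[i]
    # ancestors forced by collinearity: every placed item that must precede lab
    mustAnc <- unique(c(
      collinear$first[collinear$relation == "collinear" &
                        (collinear$a == lab | collinear$b == lab) &
                        collinear$first != lab & !is.na(collinear$first)]))
    paths <- .treePaths(root)
    placedAnc <- mustAnc[mustAnc %in% names(paths)]
    parent <- root$label
    if (length(placedAnc)) {
      # the deepest forced ancestor (they form a chain if consistent)
      depth <- vapply(placedAnc, function(a) length(paths[[a]]), numeric(1))
      parent <- placedAnc[which.max(depth)]
      chain <- paths[[parent]]
      if (!all(placedAnc %in% chain))
        stop("inconsistent collinear constraints for '", lab, "'")
    }
    f <- rest$fraction[i]
    isExclWith <- function(l)
      nrow(exclPairs) > 0 && any((exclPairs$a == lab & exclPairs$b == l) |
                                   (exclPairs$b == lab & exclPairs$a == l))
    # recursive pigeonhole descent: within a lineage the threshold is the
    # parent's fraction, not 1
    ambiguous <- FALSE
    repeat {
      pnode <- .findNode(root, parent)
      kids <- pnode$children
      if (!length(kids)) break
      kf <- vapply(kids, function(ch) ch$fraction, numeric(1))
      kl <- vapply(kids, function(ch) ch$label, character(1))
      excl <- vapply(kl, isExclWith, logical(1))
      forced <- which(kf + f > pnode$fraction + 1e-9)
      if (length(forced)) {
        j <- forced[which.max(kf[forced])]
        if (excl[j])
          stop("inconsistent constraints: '", lab,
               "' is forced to nest within its exclusive partner '",
               kl[j], "'")
        parent <- kl[j]
        next
      }
      if (sum(kf) + f > pnode$fraction + epsilon) {
        # jointly infeasible as disjoint siblings but no pair resolves the
        # order: nest under the largest admissible branch, flagged ambiguous
        cand <- which(kf >= f & !excl)
        if (!length(cand))
          stop("cannot place '", lab,
               "': lineage capacity exceeded with no admissible branch")
        parent <- kl[cand[which.max(kf[cand])]]
        ambiguous <- TRUE
        next
      }
      break
    }
    if (!ambiguous && parent == root$label && f < 1) {
      # not forced anywhere: could it nest inside an existing branch?
      couldNest <- any(vapply(root$children, function(ch)
        ch$fraction >= f && !isExclWith(ch$label), logical(1)))
      ambiguous <- couldNest
    }
    node <- .newNode(lab, rest$fraction[i], rest$nMutations[i],
                     events = if (identical(rest$type[i], "cn_event")) lab
                              else character(),
                     ambiguous = ambiguous)
    root <- .insertUnder(root, parent, node)
  }

  tree <- new("CloneTree", root = root, constraints = cons, epsilon = epsilon)
  validateTree(tree)
  tree
}

#' Verify that a clone tree satisfies its constraints
#'
#' Exhaustively checks every recorded constraint against the built tree
#' (collinear pairs are in ancestor-descendant relation with the stated
#' order; exclusive pairs are not), and that children fractions never exceed
#' their parent's by more than the tolerance.
#'
#' @param tree A \code{\link{CloneTree}}.
#' @return TRUE invisibly; errors describe any violation.
#' @export
validateTree <- function(tree) {
  paths <- .treePaths(tree@root)
  cons <- tree@constraints
  for (i in seq_len(nrow(cons))) {
    a <- cons$a[i]; b <- cons$b[i]
    if (!(a %in% names(paths)) || !(b %in% names(paths))) next
    aInB <- a %in% paths[[b]]; bInA <- b %in% paths[[a]]
    if (cons$relation[i] == "collinear") {
      if (!aInB && !bInA)
        stop(sprintf("collinear pair (%s, %s) not nested in tree", a, b))
      if (!is.na(cons$first[i])) {
        anc <- if (aInB) a else b
        if (anc != cons$first[i])
          stop(sprintf("collinear pair (%s, %s) nested in the wrong order",
                       a, b))
      }
    } else if (cons$relation[i] == "exclusive") {
      if (aInB || bInA)
        stop(sprintf("exclusive pair (%s, %s) is nested in the tree", a, b))
    }
  }
  .checkSums(tree@root, tree@epsilon)
  invisible(TRUE)
}

#' Flatten a clone tree to a data.frame
#'
#' @param tree A \code{\link{CloneTree}}.
#' @return data.frame with one row per node: \code{label}, \code{fraction},
#'   \code{nMutations}, \code{parent}, \code{depth}, \code{ambiguous}.
#' @export
treeTable <- function(tree) {
  rows <- list()
  walk <- function(node, parent, depth) {
    rows[[length(rows) + 1]] <<- data.frame(
      label = node$label, fraction = node$fraction,
      nMutations = node$nMutations, parent = parent, depth = depth,
      ambiguous = isTRUE(node$ambiguous), stringsAsFactors = FALSE)
    for (ch in node$children) walk(ch, node$label, depth + 1)
  }
  walk(tree@root, NA_character_, 0L)
  do.call(rbind, rows)
}
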