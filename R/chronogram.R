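## Time-calibrated trees. A chronogram is an ape "phylo" whose branch
## lengths are Ma; node ages are measured backwards from the youngest tip
## (present = 0), so fossil tips sit at positive ages.

#' Read a time-calibrated tree from a Newick file
#'
#' Accepts plain Newick with branch lengths in Ma.  The tree must be rooted
#' and fully bifurcating; square-bracket annotations are rejected rather
#' than silently dropped, and every branch must carry a length.  Tips need
#' not be contemporaneous: a tip whose depth is less than the maximum tip
#' depth is an extinct (fossil) tip with a positive age.
#'
#' @param path path to a Newick file; files holding several trees (one per
#'   line) yield a list of chronograms.
#' @return a `phylo` object (or list of them) that passes
#'   [validate_chronogram()].
#' @export
read_chronogram <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  check_newick_text(text)
  trees <- ape::read.tree(text = text)
  if (is.null(trees)) stop("failed to parse Newick in ", path)
  if (inherits(trees, "multiPhylo"))
    lapply(unclass(trees), validate_chronogram)
  else
    validate_chronogram(trees)
}

# cheap structural scan so that parse failures report a character position
check_newick_text <- function(text) {
  chars <- strsplit(text, "")[[1]]
  br <- which(chars == "[")
  if (length(br))
    stop("Newick annotation '[' at character position ", br[1],
         " is not supported; strip annotations first")
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' at character position ", i)
    }
  }
  if (depth != 0L)
    stop("unbalanced '(' — ", depth, " group(s) left open at character ",
         "position ", length(chars))
  if (!grepl(";\\s*$", text))
    stop("missing terminating ';' at character position ", nchar(text))
  invisible(TRUE)
}

#' Validate a chronogram
#'
#' Checks the invariants the rest of the package relies on: rooted binary
#' topology, a branch length on every edge, non-negative lengths, unique
#' tip labels.  Returns the tree invisibly augmented with nothing — node
#' ages are always recomputed from branch lengths via [node_ages()].
#'
#' @param tree a `phylo`.
#' @return the validated tree.
#' @export
validate_chronogram <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("every branch must carry a length (Ma)")
  if (any(tree$edge.length < -1e-12))
    stop("negative branch length(s) found")
  if (ape::Ntip(tree) < 2L) stop("need at least two tips")
  if (!ape::is.binary(tree))
    stop("polytomies are not supported; resolve the tree first")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Node ages in Ma before present
#'
#' Ages are root height minus root-to-node path length; the deepest tip
#' defines the present (age 0) and the root is the oldest node.
#'
#' @param tree a `phylo` with branch lengths in Ma.
#' @return numeric vector of ages indexed like ape nodes (tips
#'   `1..Ntip`, then internal nodes).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  ages[abs(ages) < 1e-12] <- 0
  ages
}

#' @rdname read_chronogram
#' @param tree a `phylo` (or list) to write.
#' @export
write_chronogram <- function(tree, path) {
  if (!inherits(tree, "phylo")) {
    tree <- structure(tree, class = "multiPhylo")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Graft a fossil tip onto a chronogram
#'
#' Inserts a new divergence node of age `divergence_age` on the stem edge
#' of `attachment` (a tip label or ape node number) and hangs a new tip of
#' age `tip_age` from it.  When `attachment` is the root, the fossil is
#' attached as sister to the whole tree under a new root of age
#' `divergence_age`, which must then exceed the current root age.  All
#' pre-existing node ages are preserved exactly.
#'
#' @param tree a validated chronogram.
#' @param attachment tip label, or integer node id in ape numbering.
#' @param tip_age age of the new tip in Ma (0 = extant).
#' @param divergence_age age of the new attachment node; must lie strictly
#'   inside the attachment edge's age interval and exceed `tip_age`.
#' @param label unique label for the new tip.
#' @return a new chronogram with one extra tip.
#' @export
graft_fossil_tip <- function(tree, attachment, tip_age, divergence_age,
                             label) {
  tree <- validate_chronogram(tree)
  if (label %in% tree$tip.label)
    stop("duplicate tip label: ", label)
  if (tip_age >= divergence_age)
    stop("tip_age (", tip_age, ") must be younger than divergence_age (",
         divergence_age, ")")
  node <- if (is.character(attachment)) {
    m <- match(attachment, tree$tip.label)
    if (is.na(m)) stop("unknown attachment tip label: ", attachment)
    m
  } else as.integer(attachment)
  ages <- node_ages(tree)
  root <- ape::Ntip(tree) + 1L
  if (node == root) {
    if (divergence_age <= ages[root])
      stop("divergence_age (", divergence_age, ") must exceed the root age (",
           ages[root], ") to attach on the root stem")
    # attach under a fresh root: the whole current tree becomes one child
    new <- ape::read.tree(text = paste0(
      "(", drop_semicolon(ape::write.tree(tree)), ":",
      format(divergence_age - ages[root], digits = 15), ",", label, ":",
      format(divergence_age - tip_age, digits = 15), ");"))
    return(validate_chronogram(new))
  }
  parent <- tree$edge[match(node, tree$edge[, 2]), 1]
  if (is.na(parent)) stop("attachment node has no stem edge")
  lo <- ages[node]; hi <- ages[parent]
  if (divergence_age <= lo || divergence_age >= hi)
    stop("divergence_age (", divergence_age, ") must lie strictly within ",
         "the attachment edge's age interval (", lo, ", ", hi, ")")
  new <- bind_tip_on_edge(tree, node, divergence_age, tip_age, label)
  validate_chronogram(new)
}

drop_semicolon <- function(x) sub(";\\s*$", "", x)

# insert a node at `divergence_age` on the stem edge of `node` and hang a
# tip of age `tip_age` from it, by direct edge surgery
bind_tip_on_edge <- function(tree, node, divergence_age, tip_age, label) {
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  edge <- tree$edge
  elen <- tree$edge.length
  # renumber: tips keep 1..ntip, new tip = ntip+1; old internal k -> k+1;
  # new internal node appended last
  shift <- function(v) ifelse(v > ntip, v + 1L, v)
  edge <- cbind(shift(edge[, 1]), shift(edge[, 2]))
  new_tip <- ntip + 1L
  new_int <- ntip + 1L + tree$Nnode + 1L
  ei <- match(shift(node), edge[, 2])
  parent <- edge[ei, 1]
  child <- edge[ei, 2]
  edge[ei, ] <- c(parent, new_int)
  elen[ei] <- elen[ei] - (divergence_age - ages[node])
  edge <- rbind(edge,
                c(new_int, child),
                c(new_int, new_tip))
  elen <- c(elen,
            divergence_age - ages[node],
            divergence_age - tip_age)
  out <- list(edge = edge, edge.length = elen,
              tip.label = c(tree$tip.label, label),
              Nnode = tree$Nnode + 1L)
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  out
}

#' Remove a tip from a chronogram
#'
#' Thin wrapper over [ape::drop.tip()]; the inverse of
#' [graft_fossil_tip()].
#'
#' @param tree a chronogram.
#' @param label tip label to remove.
#' @return the pruned chronogram.
#' @export
prune_tip <- function(tree, label) {
  if (!label %in% tree$tip.label) stop("no tip labelled ", label)
  validate_chronogram(ape::drop.tip(tree, label))
}

## ---- lineage-through-time -------------------------------------------------

#' Lineage-through-time curve
#'
#' Step function of the number of reconstructed lineages against age.  The
#' curve starts at 2 immediately after the root split; each later internal
#' node adds a lineage and each extinct tip removes one, so for trees with
#' fossil tips the count can decrease toward the present.
#'
#' @param tree a chronogram, or a list of them (each gets its own curve).
#' @param tol tip ages below `tol` Ma count as extant; the default (1e-6
#'   Ma, about a year) absorbs the precision loss of Newick round-trips.
#' @return a data frame of class `ltt_curve` with columns `age_start`,
#'   `age_end` (Ma, `age_start > age_end`) and `count`; for a list input, a
#'   list of such frames.
#' @examples
#' tr <- ape::read.tree(text = "((A:5,B:5):5,(C:5,D:5):5);")
#' ltt_curve(tr)
#' @export
ltt_curve <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) {
    return(lapply(tree, ltt_curve, tol = tol))
  }
  tree <- validate_chronogram(tree)
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  ev_age <- c(ages[internal], ages[seq_len(ntip)][ages[seq_len(ntip)] > tol])
  ev_delta <- c(rep(1L, length(internal)),
                rep(-1L, sum(ages[seq_len(ntip)] > tol)))
  ord <- order(-ev_age, -ev_delta)
  ev_age <- ev_age[ord]; ev_delta <- ev_delta[ord]
  # merge events at (numerically) identical ages
  grp <- cumsum(c(TRUE, diff(ev_age) < -tol))
  age_u <- tapply(ev_age, grp, `[`, 1)
  delta_u <- tapply(ev_delta, grp, sum)
  count <- 1L + cumsum(delta_u)
  breaks <- c(as.numeric(age_u), 0)
  out <- data.frame(age_start = breaks[-length(breaks)],
                    age_end = breaks[-1],
                    count = as.integer(count))
  out <- out[out$age_start > out$age_end, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ltt_curve", "data.frame")
  out
}

#' @export
print.ltt_curve <- function(x, ...) {
  cat("Lineage-through-time curve:", nrow(x), "intervals, root age",
      format(max(x$age_start), digits = 6), "Ma, final count",
      x$count[nrow(x)], "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.ltt_curve <- function(x, xlab = "Age (Ma)", ylab = "Lineages",
                           ...) {
  graphics::plot(c(x$age_start, 0), c(x$count, x$count[nrow(x)]),
                 type = "s", xlim = rev(range(c(x$age_start, 0))),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Write LTT curves to TSV
#'
#' @param curves an `ltt_curve` or list of them.
#' @param path output file; columns tree, age_start, age_end, count.
#' @export
write_ltt_tsv <- function(curves, path) {
  if (inherits(curves, "ltt_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(seq_along(curves), function(i) {
    cbind(tree = i, as.data.frame(curves[[i]]))
  }))
  write_tsv_c(rows, path)
  invisible(path)
}

# deterministic TSV writer: '.' decimal, fixed significant digits
write_tsv_c <- function(df, path, digits = 10) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}
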