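#' Define a set of biogeographic areas with pairwise scopes
#'
#' An area set is an ordered list of short area codes together with a
#' symmetric classification of every unordered pair of distinct areas as
#' either `"adjacent"` (same landmass or a minor barrier) or
#' `"intercontinental"` (separated by an ocean or major barrier).  The pair
#' scope drives the classification of dispersal and vicariance events.
#'
#' @param codes character vector of unique area codes, e.g. `c("EA", "EU")`.
#' @param adjacent list of length-2 character vectors naming the adjacent
#'   pairs; every pair not listed is intercontinental.
#' @return An object of class `area_set` with elements `codes`, `n` and
#'   `scope`, a symmetric character matrix with `NA` on the diagonal.
#' @examples
#' areas <- area_set(c("A", "B", "C"), adjacent = list(c("A", "B")))
#' classify_pair(areas, "A", "B")
#' @seealso [fraxinus_areas()] for the default six Northern-Hemisphere
#'   regions.
#' @export
area_set <- function(codes, adjacent = list()) {
  codes <- as.character(codes)
  if (anyDuplicated(codes)) stop("area codes must be unique")
  if (length(codes) < 1L) stop("need at least one area code")
  n <- length(codes)
  scope <- matrix("intercontinental", n, n, dimnames = list(codes, codes))
  diag(scope) <- NA_character_
  for (p in adjacent) {
    p <- as.character(p)
    if (length(p) != 2L || p[1] == p[2])
      stop("each adjacent entry must name two distinct areas")
    if (!all(p %in% codes))
      stop("unknown area code(s) in adjacency list: ",
           paste(setdiff(p, codes), collapse = ", "),
           " (valid codes: ", paste(codes, collapse = ", "), ")")
    scope[p[1], p[2]] <- "adjacent"
    scope[p[2], p[1]] <- "adjacent"
  }
  structure(list(codes = codes, n = n, scope = scope), class = "area_set")
}

#' Default six-region area set for Northern-Hemisphere disjunct floras
#'
#' Western North America (WNA), eastern North America (ENA), Japan (JP),
#' Europe (EU), East Asia (EA) and Central Asia (CA).  Adjacent pairs are
#' the within-landmass or narrow-barrier pairs WNA-ENA, EA-JP, EA-CA, JP-CA
#' and EU-CA; all remaining pairs are intercontinental.  The EU-CA and JP-CA
#' assignments are configurable defaults rather than fixed facts; rebuild
#' the set with [area_set()] to change them.
#'
#' @return An `area_set` over the six regions.
#' @export
fraxinus_areas <- function() {
  area_set(c("WNA", "ENA", "JP", "EU", "EA", "CA"),
           adjacent = list(c("WNA", "ENA"), c("EA", "JP"), c("EA", "CA"),
                           c("JP", "CA"), c("EU", "CA")))
}

#' @export
print.area_set <- function(x, ...) {
  cat("Area set:", paste(x$codes, collapse = ", "), "\n")
  adj <- which(upper.tri(x$scope) & x$scope == "adjacent", arr.ind = TRUE)
  if (nrow(adj)) {
    cat("Adjacent pairs:",
        paste(x$codes[adj[, 1]], x$codes[adj[, 2]], sep = "-",
              collapse = ", "), "\n")
  } else cat("All pairs intercontinental\n")
  invisible(x)
}

#' Classify a pair of areas as adjacent or intercontinental
#'
#' @param areas an [area_set()].
#' @param a,b distinct area codes.
#' @return `"adjacent"` or `"intercontinental"`.
#' @export
classify_pair <- function(areas, a, b) {
  stopifnot(inherits(areas, "area_set"))
  bad <- setdiff(c(a, b), areas$codes)
  if (length(bad))
    stop("unknown area code(s): ", paste(bad, collapse = ", "),
         " (valid codes: ", paste(areas$codes, collapse = ", "), ")")
  if (a == b) stop("pair scope is undefined for identical areas: ", a)
  areas$scope[a, b]
}

## ---- range states as bitmasks over the area order -------------------------

#' Enumerate the range state space
#'
#' Ranges are subsets of the area set, encoded as bitmasks over the area
#' order (bit i set = area i present).  The state space lists the null
#' (empty) range first, then all nonempty subsets of size up to
#' `max_range_size`, ordered by size and then by ascending bitmask.  The
#' null range is representable (it is the absorbing state of the
#' anagenetic process) but never observable at a tip.
#'
#' @param areas an [area_set()].
#' @param max_range_size largest permitted range size; default no cap.
#' @return An object of class `state_space` with elements `areas`, `masks`
#'   (integer bitmasks, first element 0), `sizes`, `labels`
#'   (e.g. `"EA+EU"`, `"(null)"`), `max_range_size` and `lookup`
#'   (mask -> index, 0 where a mask is excluded by the size cap).
#' @examples
#' sp <- state_space(area_set(c("A", "B", "C")), max_range_size = 2)
#' length(sp$masks)  # 1 + 3 + 3
#' @export
state_space <- function(areas, max_range_size = areas$n) {
  stopifnot(inherits(areas, "area_set"))
  if (max_range_size < 1L || max_range_size > areas$n)
    stop("max_range_size must be between 1 and ", areas$n)
  all_masks <- 0:(2L^areas$n - 1L)
  sizes <- vapply(all_masks, mask_size, integer(1))
  keep <- sizes <= max_range_size
  masks <- all_masks[keep]
  ord <- order(sizes[keep], masks)
  masks <- masks[ord]
  lookup <- integer(2L^areas$n)
  lookup[masks + 1L] <- seq_along(masks)
  structure(list(
    areas = areas,
    masks = masks,
    sizes = sizes[keep][ord],
    labels = vapply(masks, mask_label, character(1), areas = areas),
    max_range_size = as.integer(max_range_size),
    lookup = lookup
  ), class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space over", x$areas$n, "areas (max range size",
      x$max_range_size, "):", length(x$masks), "states\n")
  invisible(x)
}

mask_size <- function(mask) {
  n <- 0L
  while (mask > 0L) {
    n <- n + (mask %% 2L)
    mask <- mask %/% 2L
  }
  n
}

mask_areas <- function(mask, areas) {
  areas$codes[bitwAnd(mask, bitwShiftL(1L, seq_len(areas$n) - 1L)) != 0L]
}

mask_label <- function(mask, areas) {
  if (mask == 0L) "(null)" else paste(mask_areas(mask, areas), collapse = "+")
}

#' Convert between range strings and state indices
#'
#' `range_mask()` parses a comma- or plus-separated range string
#' (e.g. `"EA,JP"`) to a bitmask; `state_index()` maps a mask to its index
#' in a state space; `state_label()` is the inverse of `range_mask()`.
#'
#' @param areas an [area_set()].
#' @param x a range string for `range_mask()`; an integer bitmask otherwise.
#' @param space a [state_space()].
#' @return integer mask, integer index, or character label.
#' @export
range_mask <- function(areas, x) {
  if (is.na(x) || !nzchar(trimws(x))) stop("empty range string")
  parts <- trimws(strsplit(x, "[,+]")[[1]])
  parts <- parts[nzchar(parts)]
  bad <- setdiff(parts, areas$codes)
  if (length(bad))
    stop("unknown area code(s): ", paste(bad, collapse = ", "),
         " (valid codes: ", paste(areas$codes, collapse = ", "), ")")
  sum(bitwShiftL(1L, match(unique(parts), areas$codes) - 1L))
}

#' @rdname range_mask
#' @export
state_index <- function(space, x) {
  idx <- space$lookup[x + 1L]
  if (any(idx == 0L))
    stop("range exceeds max_range_size or is not in the state space")
  idx
}

#' @rdname range_mask
#' @export
state_label <- function(space, x) {
  vapply(x, mask_label, character(1), areas = space$areas)
}

## ---- transition scopes ----------------------------------------------------

#' Scope of a dispersal or vicariance transition
#'
#' Dispersal into area `b` from a source range is `"adjacent"` when at
#' least one source area is adjacent to `b` (the nearest-corridor rule, so
#' an event is never double-counted), otherwise `"intercontinental"`.  A
#' vicariance split is `"intercontinental"` when at least one
#' cross-partition pair of areas is intercontinental, otherwise
#' `"adjacent"`.
#'
#' @param areas an [area_set()].
#' @param source integer bitmask of the source (or parent) range.
#' @param gained for dispersal: bitmask of the single gained area.
#' @param partition for vicariance: length-2 list/vector of daughter
#'   bitmasks that partition the parent.
#' @return `"adjacent"` or `"intercontinental"`.
#' @examples
#' areas <- fraxinus_areas()
#' transition_scope(areas, range_mask(areas, "EA"),
#'                  gained = range_mask(areas, "EU"))
#' @export
transition_scope <- function(areas, source, gained = NULL, partition = NULL) {
  stopifnot(inherits(areas, "area_set"))
  if (!is.null(gained)) {
    if (mask_size(gained) != 1L) stop("gained must be a single area")
    if (bitwAnd(source, gained) != 0L) stop("gained area already in source")
    if (source == 0L) stop("dispersal source range must be nonempty")
    b <- mask_areas(gained, areas)
    src <- mask_areas(source, areas)
    if (any(areas$scope[src, b] == "adjacent")) "adjacent"
    else "intercontinental"
  } else if (!is.null(partition)) {
    l <- partition[[1]]; r <- partition[[2]]
    if (bitwAnd(l, r) != 0L || bitwOr(l, r) != source || l == 0L || r == 0L)
      stop("partition must split the parent range into two disjoint, ",
           "nonempty daughter ranges")
    la <- mask_areas(l, areas); ra <- mask_areas(r, areas)
    if (any(areas$scope[la, ra, drop = FALSE] == "intercontinental"))
      "intercontinental"
    else "adjacent"
  } else stop("supply either `gained` or `partition`")
}

#' Read a tip-range table
#'
#' Reads a two-column TSV mapping tip labels to comma-separated area codes
#' (e.g. `sp1<TAB>EA,JP`) and returns a named integer vector of range
#' bitmasks.
#'
#' @param path TSV file with columns tip, range (header optional; detected).
#' @param areas an [area_set()].
#' @return named integer vector of bitmasks.
#' @export
read_tip_ranges <- function(path, areas) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("tip", "range"))
  if (nrow(raw) && tolower(raw$tip[1]) %in% c("tip", "label") &&
      tolower(raw$range[1]) %in% c("range", "areas"))
    raw <- raw[-1, , drop = FALSE]
  if (anyDuplicated(raw$tip))
    stop("duplicate tip labels in range table: ",
         paste(unique(raw$tip[duplicated(raw$tip)]), collapse = ", "))
  masks <- vapply(raw$range, function(r) range_mask(areas, r), integer(1))
  stats::setNames(as.integer(masks), raw$tip)
}

#' @rdname read_tip_ranges
#' @param ranges named integer vector of bitmasks.
#' @export
write_tip_ranges <- function(ranges, areas, path) {
  lab <- vapply(ranges, function(m)
    paste(mask_areas(m, areas), collapse = ","), character(1))
  utils::write.table(data.frame(tip = names(ranges), range = lab),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
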