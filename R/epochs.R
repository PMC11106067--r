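#' Time-stratified dispersal multiplier schedule
#'
#' Encodes piecewise-constant connectivity between areas: the time axis is
#' cut at `boundaries` (ages in Ma, strictly decreasing) into
#' `length(boundaries) + 1` epochs, oldest first, and each epoch carries a
#' full matrix of per-ordered-pair dispersal multipliers in `[0, 1]`.  A
#' multiplier of 1 leaves the base dispersal rate untouched, 0 closes the
#' corridor.  An age exactly on a boundary belongs to the older epoch.
#'
#' Every off-diagonal entry must be supplied explicitly (the diagonal is
#' unused); this avoids silent defaults drifting between analyses.
#'
#' @param areas an [area_set()].
#' @param boundaries numeric ages in Ma, strictly decreasing, all > 0; may
#'   be empty for a single epoch.
#' @param multipliers list of `length(boundaries) + 1` square numeric
#'   matrices (oldest epoch first) with dimnames equal to the area codes.
#' @return an object of class `epoch_schedule`.
#' @seealso [fraxinus_epochs()], [uniform_epochs()]
#' @export
epoch_schedule <- function(areas, boundaries, multipliers) {
  stopifnot(inherits(areas, "area_set"))
  boundaries <- as.numeric(boundaries)
  if (length(boundaries)) {
    if (any(diff(boundaries) >= 0))
      stop("epoch boundaries must be strictly decreasing (oldest first)")
    if (any(boundaries <= 0)) stop("epoch boundaries must be positive ages")
  }
  if (!is.list(multipliers) ||
      length(multipliers) != length(boundaries) + 1L)
    stop("need exactly ", length(boundaries) + 1L,
         " multiplier matrices (one per epoch, oldest first)")
  multipliers <- lapply(multipliers, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == areas$n))
      stop("each multiplier matrix must be ", areas$n, "x", areas$n)
    if (is.null(dimnames(m))) {
      dimnames(m) <- list(areas$codes, areas$codes)
    } else {
      if (!identical(rownames(m), areas$codes) ||
          !identical(colnames(m), areas$codes))
        m <- m[areas$codes, areas$codes]
    }
    off <- m[row(m) != col(m)]
    if (anyNA(off))
      stop("every area pair needs a multiplier in every epoch")
    if (any(off < 0 | off > 1))
      stop("dispersal multipliers must lie in [0, 1]")
    diag(m) <- 0
    m
  })
  structure(list(areas = areas, boundaries = boundaries,
                 multipliers = multipliers),
            class = "epoch_schedule")
}

#' Single-epoch schedule with constant multipliers
#'
#' @param areas an [area_set()].
#' @param value multiplier applied to every pair (default 1, unconstrained).
#' @return an `epoch_schedule` with no boundaries.
#' @export
uniform_epochs <- function(areas, value = 1) {
  m <- matrix(value, areas$n, areas$n,
              dimnames = list(areas$codes, areas$codes))
  epoch_schedule(areas, numeric(0), list(m))
}

#' Three-slice land-bridge schedule for the six-region analysis
#'
#' Encodes the continental-connectivity history used for Northern
#' Hemisphere tree genera: before 30 Ma the North Atlantic and Bering land
#' bridges are fully open (all multipliers 1); between 30 and 5 Ma the
#' North Atlantic bridge weakens (EU-WNA multiplier 0.5); after 5 Ma the
#' North Atlantic bridge is nearly severed and the Bering bridge weakened
#' (ENA-EU 0.25, WNA-EA 0.5).  All other pairs stay at 1 in every slice.
#'
#' @param areas an [area_set()] over the six codes of [fraxinus_areas()].
#' @return an `epoch_schedule` with boundaries at 30 and 5 Ma.
#' @export
fraxinus_epochs <- function(areas = fraxinus_areas()) {
  base <- matrix(1, areas$n, areas$n,
                 dimnames = list(areas$codes, areas$codes))
  m1 <- base
  m2 <- base
  m2["EU", "WNA"] <- m2["WNA", "EU"] <- 0.5
  m3 <- base
  m3["ENA", "EU"] <- m3["EU", "ENA"] <- 0.25
  m3["WNA", "EA"] <- m3["EA", "WNA"] <- 0.5
  epoch_schedule(areas, c(30, 5), list(m1, m2, m3))
}

#' @export
print.epoch_schedule <- function(x, ...) {
  k <- length(x$multipliers)
  cat("Epoch schedule:", k, "epoch(s)")
  if (length(x$boundaries))
    cat(", boundaries at", paste(x$boundaries, collapse = ", "), "Ma")
  cat("\n")
  invisible(x)
}

#' Epoch index containing an age
#'
#' @param epochs an [epoch_schedule()].
#' @param age age in Ma; an age exactly on a boundary belongs to the older
#'   epoch.
#' @return integer epoch index (1 = oldest).
#' @export
epoch_at <- function(epochs, age) {
  vapply(age, function(a) 1L + sum(a < epochs$boundaries), integer(1))
}

# split the age interval (start_age, end_age), start older, at every epoch
# boundary it crosses; returns parallel vectors of segments oldest first
# with their epoch indices (plain list: this sits in the likelihood hot
# path)
epoch_segments <- function(epochs, start_age, end_age) {
  if (start_age < end_age)
    stop("inverted ages: start_age (", start_age,
         ") must be >= end_age (", end_age, ")")
  b <- epochs$boundaries
  if (!length(b)) {
    return(list(from = start_age, to = end_age,
                epoch = 1L, n = 1L))
  }
  cuts <- b[b < start_age & b > end_age]
  pts <- c(start_age, cuts, end_age)
  from <- pts[-length(pts)]
  to <- pts[-1]
  mid <- (from + to) / 2
  list(from = from, to = to,
       epoch = 1L + colSums(outer(b, mid, `>`)), n = length(from))
}
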