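# Run code under a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

unit3 <- function(v) v / sqrt(sum(v^2))

# any unit vector perpendicular to the unit axis
any_perp <- function(axis) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  unit3(ref - sum(ref * axis) * axis)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Ideal element C-alpha traces. Helix: radius 2.3 A, rise 1.5 A/residue,
# 100 degrees/residue. Strand: axial rise 3.3 A with +-0.9 A lateral
# alternation (a near-straight zigzag).
element_coords <- function(type, n, origin, axis) {
  axis <- unit3(axis)
  u <- any_perp(axis)
  v <- cross3(axis, u)
  t <- seq_len(n) - 1L
  if (type == "H") {
    ang <- t * 100 * pi / 180
    pts <- outer(t * 1.5, axis) + 2.3 * (outer(cos(ang), u) + outer(sin(ang), v))
  } else {
    pts <- outer(t * 3.3, axis) + outer(0.9 * (-1)^t, u)
  }
  sweep(pts, 2, origin, "+")
}

#' Build a synthetic toy fold from ideal secondary-structure geometry
#'
#' Elements are generated with ideal C-alpha geometry (helix: radius 2.3,
#' rise 1.5 A/residue, 100 degrees/residue; strand: 3.3 A axial rise with
#' +-0.9 A lateral zigzag) at the stated placements; consecutive elements
#' are connected by smooth quadratic-arc loops. A deterministic sub-0.2 A
#' perturbation keyed to the seed breaks the exact degeneracies of ideal
#' geometry.
#'
#' @param spec list with `elements` (list of `list(type, length, origin,
#'   axis)`), `loop_length` (single value or one per junction, >= 2) and
#'   `seed`.
#' @return a `protein_ca` (chain "A", residues numbered from 1).
#' @export
make_toy_structure <- function(spec) {
  stopifnot(length(spec$elements) >= 1L)
  loops <- spec$loop_length
  if (length(loops) == 1L) loops <- rep(loops, max(length(spec$elements) - 1L, 0L))
  stopifnot(all(loops >= 2L))
  el_xyz <- lapply(spec$elements, function(e) {
    stopifnot(e$type %in% c("H", "E"))
    element_coords(e$type, e$length, e$origin, e$axis)
  })
  coords <- el_xyz[[1L]]
  in_element <- rep(TRUE, nrow(coords))
  for (e in seq_along(loops)) {
    a <- el_xyz[[e]][nrow(el_xyz[[e]]), ]
    b <- el_xyz[[e + 1L]][1L, ]
    # quadratic arc bulging away from the a-b axis, sampled at equal arc
    # length so consecutive loop spacings stay uniform
    mid <- (a + b) / 2 + 2.5 * any_perp(unit3(b - a + 1e-9))
    tt <- seq(0, 1, length.out = 201L)
    dense <- outer((1 - tt)^2, a) + outer(2 * tt * (1 - tt), mid) + outer(tt^2, b)
    arc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
    want <- seq(0, arc[201L], length.out = loops[e] + 2L)[2:(loops[e] + 1L)]
    loop <- dense[vapply(want, function(s) which.min(abs(arc - s)), 0L), ,
                  drop = FALSE]
    coords <- rbind(coords, loop, el_xyz[[e + 1L]])
    in_element <- c(in_element, rep(FALSE, nrow(loop)),
                    rep(TRUE, nrow(el_xyz[[e + 1L]])))
  }
  pert <- with_seed(spec$seed %||% 0L,
                    matrix(stats::runif(length(coords), -0.1, 0.1), nrow(coords), 3L))
  coords <- coords + pert
  n <- nrow(coords)
  d <- sqrt(rowSums((coords[-1L, , drop = FALSE] - coords[-n, , drop = FALSE])^2))
  # strict virtual-bond geometry inside elements; loops only need to stay
  # connected (no spurious chain break on re-read) and non-collapsed
  elem_pair <- in_element[-1L] & in_element[-n]
  if (any(d[elem_pair] < 3.4) || any(d[elem_pair] > 4.2) ||
      any(d < 1.2) || any(d > 4.4)) {
    stop("toy fold generation failed: consecutive C-alpha spacing out of range (",
         sprintf("%.2f-%.2f A", min(d), max(d)), "); adjust placements or loop lengths")
  }
  atoms <- data.frame(chain = "A", resno = seq_len(n), insert = "", resid = "ALA",
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      stringsAsFactors = FALSE)
  new_protein_ca(atoms, label = sprintf("toy_seed%d", spec$seed %||% 0L),
                 breaks = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random toy fold specification
#'
#' Draws 3-6 elements (helices of 10-16 residues, strands of 7-12) placed on
#' a line with alternating up/down axes (so consecutive elements connect at
#' nearby ends, as in antiparallel packing), with lateral spacing of 5-9 A
#' and loop lengths derived from the junction distances. Total size falls in
#' roughly 40-120 residues. Element lengths are chosen so the interior of
#' every element (the part whose i-2..i+2 distance pattern is measurable)
#' still clears the minimum detectable run lengths of the C-alpha
#' secondary-structure assignment.
#'
#' @param seed integer seed (also stored in the spec, so the perturbation of
#'   [make_toy_structure()] is reproducible).
#' @param n_elements optional element count (default: drawn from 3:6).
#' @return a spec list consumable by [make_toy_structure()].
#' @export
random_toy_spec <- function(seed, n_elements = NULL) {
  with_seed(seed, {
    ne <- n_elements %||% sample(3:6, 1L)
    repeat {
      types <- sample(c("H", "E"), ne, replace = TRUE)
      lens <- ifelse(types == "H", sample(10:16, ne, replace = TRUE),
                     sample(7:12, ne, replace = TRUE))
      if (sum(lens) + 2L * (ne - 1L) >= 40L) break
    }
    rises <- ifelse(types == "H", 1.5, 3.3)
    extents <- (lens - 1L) * rises
    x <- cumsum(c(0, stats::runif(ne - 1L, 5, 9)))
    y <- stats::runif(ne, -1.5, 1.5)
    elements <- vector("list", ne)
    for (e in seq_len(ne)) {
      up <- e %% 2L == 1L
      z0 <- if (up) -extents[e] / 2 else extents[e] / 2
      axis <- c(0, 0, if (up) 1 else -1)
      elements[[e]] <- list(type = types[e], length = lens[e],
                            origin = c(x[e], y[e], z0), axis = axis)
    }
    # loop length from the actual terminal C-alpha positions (helix C-alphas
    # sit 2.3 A off the axis), keeping loop spacing near 2.4-3.4 A
    coords <- lapply(elements, function(e)
      element_coords(e$type, e$length, e$origin, e$axis))
    loops <- integer(ne - 1L)
    for (e in seq_len(ne - 1L)) {
      a <- coords[[e]][lens[e], ]
      b <- coords[[e + 1L]][1L, ]
      d <- sqrt(sum((b - a)^2))
      arc <- 2 * sqrt((d / 2)^2 + 2.5^2)  # chord through the loop bulge
      loops[e] <- max(2L, as.integer(round(arc / 2.8)) - 1L)
    }
    list(elements = elements, loop_length = loops, seed = seed)
  })
}

#' Permute the segment order of a structure
#'
#' Emulates the construction of non-sequential benchmark pairs: the chain is
#' split at the midpoint of every maximal coil run between consecutive
#' secondary-structure elements, the segment order is shuffled (resampled
#' until non-identity), residue numbers are reassigned in the new order, and
#' coordinates are left untouched. The permuted structure carries a
#' continuity break at every new segment junction.
#'
#' @param structure a `protein_ca`.
#' @param labels three-state labels for `structure`.
#' @param seed integer seed for the shuffle.
#' @return list with `structure` (permuted `protein_ca`) and `record`
#'   (class `permutation_record`: `segment_boundaries`, `new_order`, and
#'   `mapping`, the bijection original index -> permuted index).
#' @export
permute_segments <- function(structure, labels, seed) {
  n <- n_residues(structure)
  ann <- extract_sses(labels, structure)
  sses <- ann$sses
  cuts <- integer(0)
  if (nrow(sses) >= 2L) {
    for (s in seq_len(nrow(sses) - 1L)) {
      a <- sses$end[s] + 1L
      b <- sses$start[s + 1L] - 1L
      if (b < a) next
      cuts <- c(cuts, a + (b - a) %/% 2L + ((b - a) %% 2L))  # midpoint residue starts the next segment
    }
  }
  starts <- sort(unique(c(1L, cuts)))
  if (length(starts) < 2L) {
    stop("cannot permute: structure has a single segment after loop splitting")
  }
  ends <- c(starts[-1L] - 1L, n)
  k <- length(starts)
  new_order <- with_seed(seed, {
    repeat {
      ord <- sample.int(k)
      if (!all(ord == seq_len(k))) break
    }
    ord
  })
  orig_idx <- unlist(lapply(new_order, function(s) seq(starts[s], ends[s])))
  mapping <- integer(n)
  mapping[orig_idx] <- seq_len(n)
  atoms <- structure$atoms[orig_idx, , drop = FALSE]
  atoms$resno <- seq_len(n)
  atoms$chain <- "A"
  atoms$insert <- ""
  rownames(atoms) <- NULL
  seg_lens <- (ends - starts + 1L)[new_order]
  breaks <- cumsum(c(1L, seg_lens[-k]))
  permuted <- new_protein_ca(atoms, label = paste0(structure$label, "_perm"),
                             breaks = breaks)
  record <- structure(list(segment_boundaries = cbind(start = starts, end = ends),
                           new_order = new_order, mapping = mapping),
                      class = "permutation_record")
  list(structure = permuted, record = record)
}

#' Remap one side of a reference alignment through a permutation record
#'
#' @param reference 2-column pair matrix whose `side` column is expressed in
#'   the original (pre-permutation) indexing.
#' @param record a `permutation_record`.
#' @param side which column of the reference refers to the permuted
#'   structure ("model", the default, or "query").
#' @return pair matrix with that column passed through the bijection.
#' @export
remap_reference <- function(reference, record, side = c("model", "query")) {
  side <- match.arg(side)
  p <- as_pair_matrix(reference)
  col <- if (side == "model") 2L else 1L
  if (any(p[, col] < 1L | p[, col] > length(record$mapping))) {
    stop("reference contains indices outside the permutation mapping")
  }
  p[, col] <- record$mapping[p[, col]]
  p
}

#' Invert a permutation record
#' @param record a `permutation_record`.
#' @return record whose mapping is the inverse bijection.
#' @export
invert_permutation <- function(record) {
  inv <- integer(length(record$mapping))
  inv[record$mapping] <- seq_along(record$mapping)
  structure(list(segment_boundaries = record$segment_boundaries,
                 new_order = order(record$new_order), mapping = inv),
            class = "permutation_record")
}
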