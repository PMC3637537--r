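#' Assign three-state secondary structure from C-alpha geometry
#'
#' Per-residue helix/strand/coil labels computed from C-alpha distances alone,
#' so C-alpha-only models are fully supported. For residue i with neighbours
#' i-2..i+2 inside one continuous stretch, the five-residue distance set
#' d(i-2,i), d(i-1,i+1), d(i,i+2) (separation 2), d(i-2,i+1), d(i-1,i+2)
#' (separation 3) and d(i-2,i+2) (separation 4) is compared against ideal
#' helix values (5.45, 5.18, 6.37 Angstrom, tolerance 2.1) and ideal strand
#' values (6.1, 10.4, 13.0, tolerance 1.42). Residues lacking the needed
#' neighbours are coil.
#'
#' @param structure a `protein_ca`.
#' @param smooth apply one smoothing pass that relabels residue i when its two
#'   flanking residues agree with each other but not with i.
#' @return character vector of labels in {"H", "E", "C"}.
#' @export
assign_secondary_structure <- function(structure, smooth = TRUE) {
  n <- n_residues(structure)
  lab <- rep("C", n)
  if (n < 5L) return(lab)
  xyz <- structure$xyz
  sid <- stretch_id(structure)

  dist2 <- function(off) {
    idx <- seq_len(n - off)
    sqrt(rowSums((xyz[idx + off, , drop = FALSE] - xyz[idx, , drop = FALSE])^2))
  }
  d2 <- dist2(2L)  # d(i, i+2)
  d3 <- dist2(3L)
  d4 <- dist2(4L)

  for (i in 3:(n - 2L)) {
    if (sid[i - 2L] != sid[i + 2L]) next
    s2 <- c(d2[i - 2L], d2[i - 1L], d2[i])        # d13, d24, d35
    s3 <- c(d3[i - 2L], d3[i - 1L])               # d14, d25
    s4 <- d4[i - 2L]                              # d15
    if (all(abs(s2 - 5.45) < 2.1) && all(abs(s3 - 5.18) < 2.1) &&
        abs(s4 - 6.37) < 2.1) {
      lab[i] <- "H"
    } else if (all(abs(s2 - 6.1) < 1.42) && all(abs(s3 - 10.4) < 1.42) &&
               abs(s4 - 13.0) < 1.42) {
      lab[i] <- "E"
    }
  }
  if (smooth && n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (sid[i - 1L] == sid[i + 1L] && lab[i - 1L] == lab[i + 1L] &&
          lab[i] != lab[i - 1L]) {
        lab[i] <- lab[i - 1L]
      }
    }
  }
  lab
}

#' Extract secondary-structure elements from per-residue labels
#'
#' Maximal runs of H or E inside one continuous stretch become elements;
#' helix runs shorter than 6 residues and strand runs shorter than 3 are
#' discarded at the element level (their residues keep their three-state
#' label for the residue-level similarity).
#'
#' @param labels character vector from [assign_secondary_structure()].
#' @param structure the matching `protein_ca`.
#' @return list with `labels` (unchanged) and `sses`, a data frame with
#'   columns type ("H"/"E"), start, end (1-based inclusive residue indices).
#' @export
extract_sses <- function(labels, structure) {
  n <- n_residues(structure)
  stopifnot(length(labels) == n)
  sid <- stretch_id(structure)
  key <- paste(labels, sid)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  type <- labels[starts]
  len <- r$lengths
  keep <- (type == "H" & len >= 6L) | (type == "E" & len >= 3L)
  list(labels = labels,
       sses = data.frame(type = type[keep], start = starts[keep],
                         end = ends[keep], stringsAsFactors = FALSE))
}

# Window length of a short SSE segment per element type.
sssse_window <- function(type) ifelse(type == "H", 6L, 3L)

#' Build the set of short-segment comparing elements (CESS)
#'
#' Every element of length n contributes one comparing element per sliding
#' short-segment window (6 consecutive residues for helices, 3 for strands),
#' i.e. n-5 elements for helices and n-2 for strands. Each comparing element
#' carries: the window midpoint `r` (mean of the two end points, which for
#' helices are axial points weighted 0.74/1/1/0.74 over 3.48 and for strands
#' are midpoints of consecutive residues), the N-to-C direction `vpara`, and
#' a unit vector `vperp` perpendicular to `vpara` pointing toward the window
#' centre. Multiple elements per SSE capture the bend and twist of long
#' elements.
#'
#' @param structure a `protein_ca`.
#' @param annotation result of [extract_sses()].
#' @return object of class `cess_set`: list with parallel vectors/matrices
#'   `type`, `sse`, `k` (window start residue), `r`, `vpara`, `vperp` and `n`.
#' @export
build_cess_set <- function(structure, annotation) {
  xyz <- structure$xyz
  type <- character(0); sse <- integer(0); kvec <- integer(0)
  rr <- vp <- vq <- matrix(0, 0L, 3L)
  sses <- annotation$sses
  for (s in seq_len(nrow(sses))) {
    w <- sssse_window(sses$type[s])
    for (k in seq(sses$start[s], sses$end[s] - w + 1L)) {
      if (sses$type[s] == "H") {
        r_init <- (0.74 * xyz[k, ] + xyz[k + 1L, ] + xyz[k + 2L, ] +
                     0.74 * xyz[k + 3L, ]) / 3.48
        r_end <- (0.74 * xyz[k + 2L, ] + xyz[k + 3L, ] + xyz[k + 4L, ] +
                    0.74 * xyz[k + 5L, ]) / 3.48
        r_pdef <- (xyz[k + 2L, ] + xyz[k + 3L, ]) / 2
      } else {
        r_init <- (xyz[k, ] + xyz[k + 1L, ]) / 2
        r_end <- (xyz[k + 1L, ] + xyz[k + 2L, ]) / 2
        r_pdef <- xyz[k + 1L, ]
      }
      axis <- r_end - r_init
      axis_len <- sqrt(sum(axis^2))
      if (axis_len < 1e-9) {
        warning("degenerate short-segment direction at residue ", k, "; skipped")
        next
      }
      vpara <- axis / axis_len
      r_cess <- (r_init + r_end) / 2
      perp <- perpendicular_component(r_pdef - r_cess, vpara)
      type <- c(type, sses$type[s]); sse <- c(sse, s); kvec <- c(kvec, k)
      rr <- rbind(rr, r_cess); vp <- rbind(vp, vpara); vq <- rbind(vq, perp)
    }
  }
  structure(list(type = type, sse = sse, k = kvec,
                 r = unname(rr), vpara = unname(vp), vperp = unname(vq),
                 n = length(type)),
            class = "cess_set")
}

# Unit component of v perpendicular to the unit vector axis. Falls back to a
# fixed global direction for exactly degenerate (perfectly straight
# synthetic) geometries so the result stays deterministic.
perpendicular_component <- function(v, axis) {
  perp <- v - sum(v * axis) * axis
  nrm <- sqrt(sum(perp^2))
  if (nrm < 1e-6) {
    for (fallback in list(c(0, 0, 1), c(0, 1, 0))) {
      perp <- fallback - sum(fallback * axis) * axis
      nrm <- sqrt(sum(perp^2))
      if (nrm >= 1e-6) break
    }
  }
  perp / nrm
}

#' Build one orthonormal reference frame per comparing element
#'
#' The frame origin sits on the element point; x is the parallel (N-to-C)
#' vector, y the perpendicular vector re-orthogonalized against x, and
#' z = x cross y (right-handed).
#'
#' @param cess a `cess_set`.
#' @return object of class `frame_set`: list of n x 3 matrices `origin`, `x`,
#'   `y`, `z` and count `n`.
#' @export
build_reference_frames <- function(cess) {
  n <- cess$n
  xs <- cess$vpara
  ys <- matrix(0, n, 3L)
  zs <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    y <- perpendicular_component(cess$vperp[i, ], xs[i, ])
    x <- xs[i, ]
    ys[i, ] <- y
    zs[i, ] <- c(x[2] * y[3] - x[3] * y[2],
                 x[3] * y[1] - x[1] * y[3],
                 x[1] * y[2] - x[2] * y[1])
  }
  structure(list(origin = cess$r, x = xs, y = ys, z = zs, n = n),
            class = "frame_set")
}

# 3x3 basis matrix (columns = axes) of frame i.
frame_basis <- function(frames, i) {
  cbind(frames$x[i, ], frames$y[i, ], frames$z[i, ])
}
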