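cell_key <- function(type, abc) {
  paste(type, abc[, 1], abc[, 2], abc[, 3], sep = ":")
}

# In-frame description of all comparing elements relative to frame i:
# coordinates, parallel and perpendicular vectors expressed in frame i.
cess_in_frame <- function(cess, frames, i) {
  basis <- frame_basis(frames, i)
  list(coord = sweep(cess$r, 2, frames$origin[i, ]) %*% basis,
       vpara = cess$vpara %*% basis,
       vperp = cess$vperp %*% basis)
}

#' Build the geometric hash table for the model structure
#'
#' For every ordered pair of comparing elements (i, j), j != i, element j is
#' expressed in the reference frame of element i and stored in the voxel cell
#' `floor(coordinate / h)` under its element type. Each entry records the
#' basis frame index and the in-frame parallel and perpendicular vectors, so
#' a structure with n elements produces n(n-1) entries.
#'
#' @param model_cesses `cess_set` of the model structure.
#' @param frames matching `frame_set`.
#' @param h voxel edge length in Angstrom (default 3.2).
#' @return object of class `hash_table`: list with `h`, `cells` (named list of
#'   entry matrices with columns i, vpara(3), vperp(3)), `n_frames`,
#'   `n_entries`.
#' @export
build_hash_table <- function(model_cesses, frames, h = 3.2) {
  stopifnot(h > 0)
  n <- model_cesses$n
  if (n < 2L) {
    return(structure(list(h = h, cells = list(), n_frames = n, n_entries = 0L),
                     class = "hash_table"))
  }
  keys <- character(0)
  rows <- vector("list", 0L)
  for (i in seq_len(n)) {
    inf <- cess_in_frame(model_cesses, frames, i)
    j <- setdiff(seq_len(n), i)
    abc <- floor(inf$coord[j, , drop = FALSE] / h)
    keys <- c(keys, cell_key(model_cesses$type[j], abc))
    rows <- c(rows, list(cbind(i, inf$vpara[j, , drop = FALSE],
                               inf$vperp[j, , drop = FALSE])))
  }
  entries <- do.call(rbind, rows)
  cells <- lapply(split(seq_along(keys), keys),
                  function(idx) entries[idx, , drop = FALSE])
  structure(list(h = h, cells = cells, n_frames = n,
                 n_entries = nrow(entries)),
            class = "hash_table")
}

# Vectorized vote from cosines of the parallel (theta) and perpendicular
# (phi) angles; in reverse mode |cos theta| replaces cos theta so
# antiparallel elements can still vote.
vote_from_cos <- function(cos_theta, cos_phi, reverse_mode = FALSE) {
  c0 <- 0.5  # cos(pi/3)
  ct <- if (reverse_mode) abs(cos_theta) else cos_theta
  theta_term <- pmax((ct - c0) / (1 - c0), 0)
  phi_term <- pmax((cos_phi - c0) / (1 - c0), 0)
  theta_term + phi_term
}

#' Voting score for one stored entry against a query element
#'
#' The score is Theta + Phi where Theta = (cos theta - cos(pi/3)) /
#' (1 - cos(pi/3)) for |theta| <= pi/3 and 0 otherwise (theta the angle
#' between the in-frame parallel vectors), and Phi is the analogue for the
#' perpendicular vectors. In reverse mode Theta uses |cos theta| so elements
#' running in opposite chain directions score as parallel; Phi is unchanged.
#'
#' @param entry numeric entry row or list with `vpara`/`vperp` unit vectors
#'   (in-frame model description).
#' @param query_v_para_in_frame,query_v_perp_in_frame unit 3-vectors.
#' @param reverse_mode logical.
#' @return score in [0, 2].
#' @export
voting_score <- function(entry, query_v_para_in_frame, query_v_perp_in_frame,
                         reverse_mode = FALSE) {
  if (is.list(entry)) {
    vp <- entry$vpara; vq <- entry$vperp
  } else {
    entry <- as.numeric(entry)
    vp <- entry[2:4]; vq <- entry[5:7]
  }
  vote_from_cos(sum(vp * query_v_para_in_frame),
                sum(vq * query_v_perp_in_frame), reverse_mode)
}

#' Recognition voting between a query structure and a model hash table
#'
#' Every query element l is expressed in the frame of every other query
#' element k and looked up in the model table; each stored entry of matching
#' element type adds its voting score to the accumulator of the frame pair
#' (model frame i, query frame k).
#'
#' @param query_cesses query `cess_set`.
#' @param query_frames matching `frame_set`.
#' @param table model `hash_table`.
#' @param reverse_mode allow antiparallel direction matches (mixed mode).
#' @return data frame (model_frame, query_frame, vote) sorted by vote
#'   descending, ties broken by (model_frame, query_frame) ascending.
#' @export
recognize <- function(query_cesses, query_frames, table, reverse_mode = FALSE) {
  empty <- data.frame(model_frame = integer(0), query_frame = integer(0),
                      vote = numeric(0))
  nq <- query_cesses$n
  if (table$n_entries == 0L || nq < 2L) return(empty)
  votes <- matrix(0, table$n_frames, nq)
  for (k in seq_len(nq)) {
    inf <- cess_in_frame(query_cesses, query_frames, k)
    ls <- setdiff(seq_len(nq), k)
    abc <- floor(inf$coord[ls, , drop = FALSE] / table$h)
    keys <- cell_key(query_cesses$type[ls], abc)
    for (t in seq_along(ls)) {
      entries <- table$cells[[keys[t]]]
      if (is.null(entries)) next
      l <- ls[t]
      s <- vote_from_cos(entries[, 2:4, drop = FALSE] %*% inf$vpara[l, ],
                         entries[, 5:7, drop = FALSE] %*% inf$vperp[l, ],
                         reverse_mode)
      agg <- rowsum(as.numeric(s), entries[, 1])
      idx <- as.integer(rownames(agg))
      votes[idx, k] <- votes[idx, k] + agg[, 1]
    }
  }
  nz <- which(votes > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(empty)
  out <- data.frame(model_frame = nz[, 1], query_frame = nz[, 2],
                    vote = votes[nz])
  out <- out[order(-out$vote, out$model_frame, out$query_frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate superpositions from the top-ranked frame pairs
#'
#' For each of the top `K` frame pairs, returns the unique rigid transform
#' that superposes the model frame onto the query frame: rotation
#' `Bq %*% t(Bm)` (columns = frame axes) and translation
#' `origin_q - rotation %*% origin_m`.
#'
#' @param scores ranked data frame from [recognize()].
#' @param model_frames,query_frames `frame_set` objects.
#' @param K number of seeds to keep (default 50).
#' @return list of `superposition` objects (each tagged with its frame pair).
#' @export
top_superpositions <- function(scores, model_frames, query_frames, K = 50L) {
  m <- min(K, nrow(scores))
  if (m == 0L) return(list())
  lapply(seq_len(m), function(t) {
    i <- scores$model_frame[t]
    k <- scores$query_frame[t]
    bm <- frame_basis(model_frames, i)
    bq <- frame_basis(query_frames, k)
    rot <- bq %*% t(bm)
    new_superposition(rot,
                      query_frames$origin[k, ] - as.numeric(rot %*% model_frames$origin[i, ]),
                      source_frame_pair = c(i, k))
  })
}
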