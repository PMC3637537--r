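as_pair_matrix <- function(x) {
  if (inherits(x, "nsalign_alignment")) x <- alignment_pairs(x$segments)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.integer(x), ncol = 2L)
  storage.mode(x) <- "integer"
  unname(x[, 1:2, drop = FALSE])
}

#' Reference-dependent alignment accuracy (Q-score)
#'
#' Percentage of reference residue pairs reproduced by a test alignment:
#' `100 * |test pairs intersect reference pairs| / |reference pairs|`.
#'
#' @param test alignment (`nsalign_alignment`) or 2-column matrix of
#'   (query index, model index) pairs.
#' @param reference 2-column matrix of reference pairs (non-empty).
#' @return percentage in [0, 100].
#' @export
q_score <- function(test, reference) {
  ref <- as_pair_matrix(reference)
  if (nrow(ref) == 0L) stop("Q-score is undefined for an empty reference alignment")
  tst <- as_pair_matrix(test)
  ref_keys <- paste(ref[, 1], ref[, 2])
  tst_keys <- paste(tst[, 1], tst[, 2])
  100 * sum(ref_keys %in% tst_keys) / nrow(ref)
}

#' Decompose an alignment into consecutively aligned fragments
#'
#' Pairs are sorted by query index and greedily extended into maximal runs
#' consecutive in both structures: forward runs step (+1, +1), reverse runs
#' (+1, -1). The direction of a fragment is fixed by its first extension;
#' a lone pair is a length-1 fragment.
#'
#' @param pairs 2-column pair matrix.
#' @return data frame (start_q, start_m, len, dir) of fragments.
#' @export
decompose_fragments <- function(pairs) {
  p <- as_pair_matrix(pairs)
  out <- data.frame(start_q = integer(0), start_m = integer(0),
                    len = integer(0), dir = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(p) == 0L) return(out)
  p <- p[order(p[, 1]), , drop = FALSE]
  i <- 1L
  while (i <= nrow(p)) {
    start <- i
    dir <- NA_character_
    while (i < nrow(p) && p[i + 1L, 1] == p[i, 1] + 1L) {
      step <- p[i + 1L, 2] - p[i, 2]
      if (is.na(dir)) {
        if (step == 1L) dir <- "forward"
        else if (step == -1L) dir <- "reverse"
        else break
      } else if ((dir == "forward" && step != 1L) ||
                 (dir == "reverse" && step != -1L)) break
      i <- i + 1L
    }
    out <- rbind(out, data.frame(start_q = p[start, 1], start_m = p[start, 2],
                                 len = i - start + 1L,
                                 dir = if (is.na(dir)) "forward" else dir,
                                 stringsAsFactors = FALSE))
    i <- i + 1L
  }
  out
}

#' TM-score of a residue pairing
#'
#' `(1 / L_norm) * sum over pairs of 1 / (1 + d_ij^2 / d0(L_norm)^2)`,
#' maximized over an iterative superposition scheme: superpose on all pairs,
#' then repeatedly re-superpose on the subset of pairs closer than
#' `max(d0, 4.8)` Angstrom until the subset is stable, keeping the best
#' score seen.
#'
#' @param pairs 2-column pair matrix (at least 3 pairs).
#' @param query,model `protein_ca` structures.
#' @param normalization_length chain length used for d0 and the mean.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(pairs, query, model, normalization_length) {
  p <- as_pair_matrix(pairs)
  if (nrow(p) < 3L) stop("TM-score is undefined for fewer than 3 pairs")
  d0 <- compute_d0(normalization_length)
  qx <- query$xyz[p[, 1], , drop = FALSE]
  mx <- model$xyz[p[, 2], , drop = FALSE]
  score_under <- function(sup) {
    d2 <- rowSums((qx - apply_superposition(mx, sup))^2)
    list(tm = sum(1 / (1 + d2 / d0^2)) / normalization_length, d = sqrt(d2))
  }
  sel <- seq_len(nrow(p))
  best <- -Inf
  cutoff <- max(d0, 4.8)
  prev_sel <- integer(0)
  for (it in seq_len(20L)) {
    sup <- kabsch_superpose(qx[sel, , drop = FALSE], mx[sel, , drop = FALSE])$sup
    sc <- score_under(sup)
    if (sc$tm > best) best <- sc$tm
    new_sel <- which(sc$d < cutoff)
    if (length(new_sel) < 3L || identical(new_sel, sel) ||
        identical(new_sel, prev_sel)) break
    prev_sel <- sel
    sel <- new_sel
  }
  best
}

#' Reference-independent alignment statistics
#'
#' Decomposes the pair set into consecutively aligned fragments and reports:
#' `n_ali` (aligned pairs as a percentage of the smaller protein length),
#' `n_ali_prime` (same, excluding fragments shorter than 3 pairs), `n_gap`
#' (number of fragments minus one), the Kabsch-optimal RMSD over all pairs,
#' the TM-score, and the fragment length distribution.
#'
#' @param test alignment or 2-column pair matrix.
#' @param query,model structures.
#' @param smaller_length length of the smaller protein.
#' @param superposition optional fixed superposition for per-pair distances
#'   (RMSD is always Kabsch-optimal over the pairs).
#' @param normalization_length length for the TM-score (default
#'   `smaller_length`).
#' @return list of class `alignment_stats`.
#' @export
alignment_stats <- function(test, query, model, smaller_length,
                            superposition = NULL,
                            normalization_length = smaller_length) {
  p <- as_pair_matrix(test)
  if (nrow(p) == 0L) {
    return(structure(list(n_pairs = 0L, n_ali_percent = 0,
                          n_ali_prime_percent = 0, rmsd = NA_real_,
                          n_gap = 0L, tm_score = NA_real_,
                          fragment_lengths = integer(0)),
                     class = "alignment_stats"))
  }
  frags <- decompose_fragments(p)
  n_pairs <- nrow(p)
  long <- frags$len >= 3L
  rmsd <- kabsch_superpose(query$xyz[p[, 1], , drop = FALSE],
                           model$xyz[p[, 2], , drop = FALSE])$rmsd
  tm <- if (n_pairs >= 3L) {
    tm_score(p, query, model, normalization_length)
  } else NA_real_
  structure(list(n_pairs = n_pairs,
                 n_ali_percent = 100 * n_pairs / smaller_length,
                 n_ali_prime_percent = 100 * sum(frags$len[long]) / smaller_length,
                 rmsd = rmsd,
                 n_gap = max(nrow(frags) - 1L, 0L),
                 tm_score = tm,
                 fragment_lengths = sort(frags$len)),
            class = "alignment_stats")
}

#' Read a reference alignment from TSV
#'
#' Format: tab-separated `query_chain query_resnum model_chain model_resnum`,
#' one pair per line; lines starting with `#` are comments. Residue numbers
#' are mapped to internal indices through the two structures.
#'
#' @param path TSV file.
#' @param query,model structures used to resolve residue numbers.
#' @return 2-column matrix of (query index, model index) pairs.
#' @export
read_reference_alignment <- function(path, query, model) {
  if (!file.exists(path)) stop("reference alignment file not found: ", path)
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        data.frame()
      } else stop(e)
    })
  if (nrow(tab) == 0L) {
    return(matrix(integer(0), 0L, 2L))
  }
  if (ncol(tab) < 4L) stop("alignment TSV needs at least 4 columns (line 1)")
  names(tab)[1:4] <- c("qchain", "qres", "mchain", "mres")  # extra columns ignored
  qi <- match(paste(tab$qchain, tab$qres),
              paste(query$atoms$chain, query$atoms$resno))
  mi <- match(paste(tab$mchain, tab$mres),
              paste(model$atoms$chain, model$atoms$resno))
  bad <- which(is.na(qi) | is.na(mi))
  if (length(bad) > 0L) {
    stop("reference alignment line ", bad[1L],
         " names a residue absent from the structures")
  }
  cbind(qi, mi)
}

#' Write a reference alignment (or any pair set) as TSV
#'
#' @param pairs 2-column matrix of internal indices.
#' @param query,model structures used to recover chain/residue numbering.
#' @param path output path.
#' @export
write_reference_alignment <- function(pairs, query, model, path) {
  p <- as_pair_matrix(pairs)
  lines <- c("# query_chain\tquery_resnum\tmodel_chain\tmodel_resnum",
             sprintf("%s\t%d\t%s\t%d",
                     query$atoms$chain[p[, 1]], query$atoms$resno[p[, 1]],
                     model$atoms$chain[p[, 2]], model$atoms$resno[p[, 2]]))
  writeLines(lines, path)
  invisible(path)
}
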