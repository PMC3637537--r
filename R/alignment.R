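#' Alignment parameters
#'
#' Defaults reproduce the published parameter set of the method: distance
#' scale `R0` = voxel size `h` = 3.2 Angstrom, secondary-structure weight
#' `w` = 1, minimum segment score `s_min` = 2.2, 50 superposition seeds,
#' stepwise distance cutoffs (1, 1.5, 2.5) x R0, forward-only mode, and
#' score normalization by the query (first structure) length.
#'
#' @param R0 base distance cutoff in Angstrom.
#' @param h hash voxel size in Angstrom.
#' @param w secondary-structure type weight in the similarity.
#' @param s_min minimum accepted segment score; with cell values capped at 1
#'   this forces every accepted segment to span at least 3 residues.
#' @param top_k_seeds number of candidate superpositions to refine.
#' @param max_refine_iters hard cap on refinement iterations.
#' @param mode `"forward"` or `"mixed"` (forward + reverse segments).
#' @param d_steps strictly increasing multipliers of `R0` for the stepwise
#'   cutoff schedule.
#' @param normalization `"first_structure"` (query length) or `"shorter"`.
#' @return list of class `align_params`.
#' @export
align_params <- function(R0 = 3.2, h = 3.2, w = 1.0, s_min = 2.2,
                         top_k_seeds = 50L, max_refine_iters = 30L,
                         mode = c("forward", "mixed"),
                         d_steps = c(1.0, 1.5, 2.5),
                         normalization = c("first_structure", "shorter")) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  stopifnot(R0 > 0, h > 0, s_min > 0, all(diff(d_steps) > 0))
  structure(list(R0 = R0, h = h, w = w, s_min = s_min,
                 top_k_seeds = as.integer(top_k_seeds),
                 max_refine_iters = as.integer(max_refine_iters),
                 mode = mode, d_steps = d_steps, normalization = normalization),
            class = "align_params")
}

#' Length-dependent distance scale d0
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, clamped below at 0.5 Angstrom for short
#' chains where the raw formula is small or negative. The scale removes the
#' inherent protein-size dependence of distance-based similarity scores.
#'
#' @param L normalization length (residues).
#' @return d0 in Angstrom.
#' @export
compute_d0 <- function(L) {
  stopifnot(L >= 1)
  raw <- if (L > 15) 1.24 * (L - 15)^(1 / 3) - 1.8 else -Inf
  max(raw, 0.5)
}

#' Residue-residue similarity matrix under a superposition
#'
#' `M_ij = [1 / (1 + d_ij^2 / d0^2)] * [(delta_ij + w) / (1 + w)]` when
#' `d_ij <= d_R`, else 0; `d_ij` is the distance between query C-alpha i and
#' the transformed model C-alpha j, and `delta_ij` is 1 when the two residues
#' carry the same three-state secondary-structure label.
#'
#' @param query,model `protein_ca` structures.
#' @param query_labels,model_labels three-state label vectors.
#' @param sup `superposition` mapping model into the query frame.
#' @param d_R distance cutoff in Angstrom.
#' @param params `align_params`.
#' @return list of class `similarity_matrix` with `values` (N x M), `d_R`,
#'   `d0`, `sup`.
#' @export
similarity_matrix <- function(query, model, query_labels, model_labels,
                              sup, d_R, params = align_params()) {
  qx <- query$xyz
  mx <- apply_superposition(model$xyz, sup)
  nq <- nrow(qx); nm <- nrow(mx)
  l_norm <- if (params$normalization == "shorter") min(nq, nm) else nq
  d0 <- compute_d0(l_norm)
  d2 <- pmax(outer(rowSums(qx^2), rep(1, nm)) +
               outer(rep(1, nq), rowSums(mx^2)) - 2 * qx %*% t(mx), 0)
  type_fac <- (outer(query_labels, model_labels, "==") + params$w) / (1 + params$w)
  vals <- (1 / (1 + d2 / d0^2)) * type_fac
  vals[d2 > d_R^2] <- 0
  structure(list(values = vals, d_R = d_R, d0 = d0, sup = sup),
            class = "similarity_matrix")
}

# Enumerate maximal runs of positive, unblocked cells along forward
# diagonals (and anti-diagonals in mixed mode). Runs terminate at chain
# breaks in either structure. Returns a data frame of candidate segments
# (alpha, beta, len, dir, score). Because every in-run cell is positive, the
# best sub-segment of a run is the whole run, so maximal runs are exactly
# the candidate set for the greedy step.
segment_runs <- function(values, q_blocked, m_blocked, q_start, m_start,
                         mode = "forward") {
  nz <- which(values > 0, arr.ind = TRUE)
  if (nrow(nz) > 0L) {
    keep <- !q_blocked[nz[, 1]] & !m_blocked[nz[, 2]]
    nz <- nz[keep, , drop = FALSE]
  }
  out <- list()
  if (nrow(nz) > 0L) {
    i <- nz[, 1]; j <- nz[, 2]
    ord <- order(i - j, i)
    i <- i[ord]; j <- j[ord]
    v <- values[cbind(i, j)]
    if (length(i) > 1L) {
      new_run <- c(TRUE, diff(i - j) != 0 | diff(i) != 1L |
                     q_start[i[-1]] | m_start[j[-1]])
    } else new_run <- TRUE
    run <- cumsum(new_run)
    score <- as.numeric(rowsum(v, run))
    first <- which(new_run)
    len <- as.integer(tabulate(run))
    out$fwd <- data.frame(alpha = i[first], beta = j[first], len = len,
                          dir = "forward", score = score,
                          stringsAsFactors = FALSE)
  }
  if (mode == "mixed") {
    nz <- which(values > 0, arr.ind = TRUE)
    if (nrow(nz) > 0L) {
      keep <- !q_blocked[nz[, 1]] & !m_blocked[nz[, 2]]
      nz <- nz[keep, , drop = FALSE]
    }
    if (nrow(nz) > 0L) {
      i <- nz[, 1]; j <- nz[, 2]
      ord <- order(i + j, i)
      i <- i[ord]; j <- j[ord]
      v <- values[cbind(i, j)]
      if (length(i) > 1L) {
        # step (i, j) -> (i+1, j-1): query crosses a boundary if i+1 starts a
        # stretch; the model crosses one if j (the larger index) starts one.
        new_run <- c(TRUE, diff(i + j) != 0 | diff(i) != 1L |
                       q_start[i[-1]] | m_start[j[-length(j)]])
      } else new_run <- TRUE
      run <- cumsum(new_run)
      score <- as.numeric(rowsum(v, run))
      first <- which(new_run)
      len <- as.integer(tabulate(run))
      rev_runs <- data.frame(alpha = i[first], beta = j[first], len = len,
                             dir = "reverse", score = score,
                             stringsAsFactors = FALSE)
      rev_runs <- rev_runs[rev_runs$len >= 2L, , drop = FALSE]  # a single pair is directionless
      out$rev <- rev_runs
    }
  }
  if (length(out) == 0L) {
    return(data.frame(alpha = integer(0), beta = integer(0), len = integer(0),
                      dir = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Best continuous segment on a similarity matrix
#'
#' Returns the maximal-score run of strictly positive, unblocked entries
#' along forward diagonals (and anti-diagonals in mixed mode); runs also
#' terminate at chain breaks. Ties are broken deterministically: forward
#' before reverse, then smallest query start, then smallest model start
#' (scores compared after rounding at 1e-9 so floating-point jitter cannot
#' reorder genuine ties).
#'
#' @param matrix a `similarity_matrix`.
#' @param q_blocked,m_blocked logical masks of already-used residues.
#' @param q_start,m_start logical stretch-start masks (see `protein_ca`).
#' @param mode "forward" or "mixed".
#' @return one-row segment data frame, or NULL when no positive run exists.
#' @export
best_segment <- function(matrix, q_blocked = NULL, m_blocked = NULL,
                         q_start = NULL, m_start = NULL, mode = "forward") {
  vals <- matrix$values
  if (is.null(q_blocked)) q_blocked <- rep(FALSE, nrow(vals))
  if (is.null(m_blocked)) m_blocked <- rep(FALSE, ncol(vals))
  if (is.null(q_start)) q_start <- c(TRUE, rep(FALSE, nrow(vals) - 1L))
  if (is.null(m_start)) m_start <- c(TRUE, rep(FALSE, ncol(vals) - 1L))
  runs <- segment_runs(vals, q_blocked, m_blocked, q_start, m_start, mode)
  if (nrow(runs) == 0L) return(NULL)
  key <- order(-round(runs$score, 9), runs$dir != "forward", runs$alpha, runs$beta)
  runs[key[1L], , drop = FALSE]
}

# residue index pairs (query, model) of one segment row
segment_pairs <- function(seg) {
  m <- seq_len(seg$len) - 1L
  if (seg$dir == "forward") cbind(seg$alpha + m, seg$beta + m)
  else cbind(seg$alpha + m, seg$beta - m)
}

alignment_pairs <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0L) {
    return(matrix(integer(0), 0L, 2L))
  }
  do.call(rbind, lapply(seq_len(nrow(segments)),
                        function(s) segment_pairs(segments[s, , drop = FALSE])))
}

#' Greedy non-overlapping segment selection
#'
#' Rows and columns used by `carried_segments` are blocked first (the carried
#' segments are retained in the output); then the best remaining segment is
#' repeatedly taken, accepted iff its score is at least `s_min`, and its rows
#' and columns blocked, until no acceptable segment remains.
#'
#' @param matrix a `similarity_matrix`.
#' @param s_min minimum accepted segment score.
#' @param carried_segments segment data frame carried from a previous step.
#' @param mode "forward" or "mixed".
#' @param q_start,m_start stretch-start masks.
#' @return segment data frame (carried + newly accepted).
#' @export
greedy_select <- function(matrix, s_min = 2.2, carried_segments = NULL,
                          mode = "forward", q_start = NULL, m_start = NULL) {
  vals <- matrix$values
  nq <- nrow(vals); nm <- ncol(vals)
  q_blocked <- rep(FALSE, nq); m_blocked <- rep(FALSE, nm)
  segs <- carried_segments
  if (!is.null(segs) && nrow(segs) > 0L) {
    p <- alignment_pairs(segs)
    q_blocked[p[, 1]] <- TRUE
    m_blocked[p[, 2]] <- TRUE
  } else {
    segs <- data.frame(alpha = integer(0), beta = integer(0), len = integer(0),
                       dir = character(0), score = numeric(0),
                       stringsAsFactors = FALSE)
  }
  repeat {
    seg <- best_segment(matrix, q_blocked, m_blocked, q_start, m_start, mode)
    if (is.null(seg) || seg$score < s_min) break
    segs <- rbind(segs, seg)
    p <- segment_pairs(seg)
    q_blocked[p[, 1]] <- TRUE
    m_blocked[p[, 2]] <- TRUE
  }
  rownames(segs) <- NULL
  segs
}

new_alignment <- function(segments, sup, mtm = NA_real_,
                          total_segment_score = NA_real_, seed_rank = NA_integer_) {
  structure(list(segments = segments, superposition = sup, mtm = mtm,
                 total_segment_score = total_segment_score,
                 n_pairs = if (is.null(segments)) 0L else sum(segments$len),
                 seed_rank = seed_rank),
            class = "nsalign_alignment")
}

#' @export
print.nsalign_alignment <- function(x, ...) {
  cat(sprintf("alignment: %d segment(s), %d residue pairs, mTM = %.4f\n",
              nrow(x$segments), x$n_pairs, x$mtm))
  invisible(x)
}

#' Stepwise greedy residue alignment from one seed superposition
#'
#' Runs the greedy segment selection at cutoffs d_1 = R0, d_2 = 1.5 R0 and
#' d_3 = 2.5 R0 under the same superposition, recomputing the similarity
#' matrix at each cutoff and carrying all previously accepted segments
#' forward, so pairs matched at tight cutoffs are kept while looser cutoffs
#' extend the alignment.
#'
#' @param query,model `protein_ca` structures.
#' @param query_labels,model_labels three-state labels.
#' @param sup seed `superposition`.
#' @param params `align_params`.
#' @return `nsalign_alignment` with mTM and total segment score filled in.
#' @export
stepwise_alignment <- function(query, model, query_labels, model_labels,
                               sup, params = align_params()) {
  q_start <- stretch_start(query)
  m_start <- stretch_start(model)
  segs <- NULL
  sm <- NULL
  for (mult in params$d_steps) {
    sm <- similarity_matrix(query, model, query_labels, model_labels,
                            sup, mult * params$R0, params)
    segs <- greedy_select(sm, params$s_min, segs, params$mode, q_start, m_start)
  }
  aln <- new_alignment(segs, sup)
  aln$total_segment_score <- if (nrow(segs) > 0L) {
    sum(sm$values[alignment_pairs(segs)])
  } else 0
  aln$mtm <- mtm_score(aln, query, model, query_labels, model_labels, params)
  aln
}

#' Modified TM score of an alignment
#'
#' Mean over the normalization length of the similarity values
#' `M_ij(d_3)` of all aligned pairs under the alignment's superposition.
#'
#' @param alignment `nsalign_alignment`.
#' @param query,model structures.
#' @param query_labels,model_labels labels.
#' @param params `align_params`.
#' @return score in [0, 1].
#' @export
mtm_score <- function(alignment, query, model, query_labels, model_labels,
                      params = align_params()) {
  p <- alignment_pairs(alignment$segments)
  if (nrow(p) == 0L) return(0)
  l_norm <- if (params$normalization == "shorter") {
    min(n_residues(query), n_residues(model))
  } else n_residues(query)
  d3 <- max(params$d_steps) * params$R0
  sm <- similarity_matrix(query, model, query_labels, model_labels,
                          alignment$superposition, d3, params)
  sum(sm$values[p]) / l_norm
}

#' Iterative refinement of an alignment
#'
#' Alternates between superposing on all currently aligned pairs (Kabsch)
#' and regenerating the stepwise alignment under the new superposition,
#' until the modified TM score stops improving by more than 1e-6 or the
#' iteration cap is reached. The best-scoring iterate ever seen is returned,
#' so the result is never worse than the input.
#'
#' @param query,model structures.
#' @param query_labels,model_labels labels.
#' @param initial starting `nsalign_alignment`.
#' @param params `align_params`.
#' @return refined `nsalign_alignment`; `$iterations` records how many
#'   refinement rounds ran.
#' @export
refine_alignment <- function(query, model, query_labels, model_labels,
                             initial, params = align_params()) {
  if (is.null(initial$segments) || nrow(initial$segments) == 0L) {
    initial$iterations <- 0L
    return(initial)
  }
  best <- initial
  current <- initial
  iters <- 0L
  for (it in seq_len(params$max_refine_iters)) {
    p <- alignment_pairs(current$segments)
    sup <- kabsch_superpose(query$xyz[p[, 1], , drop = FALSE],
                            model$xyz[p[, 2], , drop = FALSE])$sup
    nxt <- stepwise_alignment(query, model, query_labels, model_labels,
                              sup, params)
    iters <- it
    improved <- nxt$mtm > best$mtm + 1e-6
    if (nxt$mtm > best$mtm) best <- nxt
    if (!improved) break
    current <- nxt
  }
  best$iterations <- iters
  best
}

segment_set_key <- function(segments) {
  if (nrow(segments) == 0L) return("")
  o <- order(segments$alpha, segments$beta)
  paste(segments$alpha[o], segments$beta[o], segments$len[o],
        segments$dir[o], sep = ":", collapse = "|")
}

#' Align a pair of protein structures
#'
#' Full pipeline: secondary-structure assignment, short-segment comparing
#' elements, geometric-hashing recognition, top-K candidate superpositions,
#' stepwise greedy residue alignment and iterative refinement from every
#' seed. Results are deduplicated by segment set and ranked by modified TM
#' score (ties: more aligned pairs, then seed rank). The best alignment is
#' annotated with reference-independent statistics.
#'
#' @param query,model `protein_ca` structures (query is the first structure;
#'   scores are normalized by its length under the default normalization).
#' @param params `align_params`.
#' @return object of class `nsalign_result`: list with `status`
#'   ("ok"/"empty"), `alignments` (ranked list), `best`, `stats`
#'   (for the best alignment), `query_labels`, `model_labels`, `n_seeds`.
#'   Structures with fewer than 2 comparing elements raise a no-SSE error
#'   (condition class `nsalign_no_sse`).
#' @export
align_pair <- function(query, model, params = align_params()) {
  q_lab <- assign_secondary_structure(query)
  m_lab <- assign_secondary_structure(model)
  q_ann <- extract_sses(q_lab, query)
  m_ann <- extract_sses(m_lab, model)
  q_cess <- build_cess_set(query, q_ann)
  m_cess <- build_cess_set(model, m_ann)
  if (q_cess$n < 2L || m_cess$n < 2L) {
    stop(structure(class = c("nsalign_no_sse", "error", "condition"),
                   list(message = paste0(
                     "too few secondary-structure elements to align (",
                     q_cess$n, " query / ", m_cess$n,
                     " model comparing elements; need >= 2 each)"),
                     call = sys.call(-1))))
  }
  q_frames <- build_reference_frames(q_cess)
  m_frames <- build_reference_frames(m_cess)
  tab <- build_hash_table(m_cess, m_frames, params$h)
  scores <- recognize(q_cess, q_frames, tab,
                      reverse_mode = params$mode == "mixed")
  seeds <- top_superpositions(scores, m_frames, q_frames, params$top_k_seeds)
  result <- structure(list(status = "empty", alignments = list(), best = NULL,
                           stats = NULL, query_labels = q_lab,
                           model_labels = m_lab, n_seeds = length(seeds)),
                      class = "nsalign_result")
  if (length(seeds) == 0L) return(result)

  # initial stepwise alignments; identical initial segment sets refine
  # identically, so refine each distinct one once (earliest seed rank kept)
  refined <- list()
  seen_initial <- character(0)
  for (rank in seq_along(seeds)) {
    ini <- stepwise_alignment(query, model, q_lab, m_lab, seeds[[rank]], params)
    if (nrow(ini$segments) == 0L) next
    key <- segment_set_key(ini$segments)
    if (key %in% seen_initial) next
    seen_initial <- c(seen_initial, key)
    ref <- refine_alignment(query, model, q_lab, m_lab, ini, params)
    ref$seed_rank <- rank
    refined <- c(refined, list(ref))
  }
  if (length(refined) == 0L) return(result)

  final_keys <- vapply(refined, function(a) segment_set_key(a$segments), "")
  refined <- refined[!duplicated(final_keys)]
  mtms <- vapply(refined, function(a) a$mtm, 0)
  npairs <- vapply(refined, function(a) a$n_pairs, 0L)
  rank_seed <- vapply(refined, function(a) a$seed_rank, 0L)
  refined <- refined[order(-round(mtms, 9), -npairs, rank_seed)]

  result$status <- "ok"
  result$alignments <- refined
  result$best <- refined[[1L]]
  result$stats <- alignment_stats(
    alignment_pairs(result$best$segments), query, model,
    smaller_length = min(n_residues(query), n_residues(model)),
    superposition = result$best$superposition,
    normalization_length = if (params$normalization == "shorter") {
      min(n_residues(query), n_residues(model))
    } else n_residues(query))
  result
}

#' @export
print.nsalign_result <- function(x, ...) {
  if (x$status != "ok") {
    cat("no alignment found (", x$status, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("best of %d distinct alignment(s) from %d seed(s):\n",
              length(x$alignments), x$n_seeds))
  print(x$best)
  if (!is.null(x$stats)) {
    cat(sprintf("TM = %.3f, RMSD = %.2f A, N_ali = %.1f%%, N'_ali = %.1f%%, N_gap = %d\n",
                x$stats$tm_score, x$stats$rmsd, x$stats$n_ali_percent,
                x$stats$n_ali_prime_percent, x$stats$n_gap))
  }
  invisible(x)
}
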