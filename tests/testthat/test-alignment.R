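test_that("d0 follows the size formula with a 0.5 A floor", {
  expect_equal(compute_d0(100), 1.24 * 85^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(compute_d0(100), 3.652, tolerance = 1e-3)
  expect_equal(compute_d0(15), 0.5)
  expect_equal(compute_d0(19), 0.5)  # raw value 0.177, clamped
  Ls <- 1:300
  expect_true(all(diff(vapply(Ls, compute_d0, 0)) >= 0))
})

test_that("similarity matrix matches the closed-form entries", {
  p <- align_params()
  q <- structure_from_xyz(rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0)))
  m <- structure_from_xyz(rbind(c(0, 0, 0), c(100, 0, p$R0 * 2.5 + 0.01),
                                c(200, 0, compute_d0(3))))
  labq <- c("H", "H", "H")
  d3 <- 2.5 * p$R0
  sm <- similarity_matrix(q, m, labq, c("H", "H", "H"), new_superposition(), d3, p)
  expect_equal(sm$d0, 0.5)  # query length 3 -> clamp
  expect_equal(sm$values[1, 1], 1)                   # d = 0, same type
  expect_equal(sm$values[2, 2], 0)                   # just beyond d_R
  sm2 <- similarity_matrix(q, m, labq, c("E", "H", "H"), new_superposition(), d3, p)
  expect_equal(sm2$values[1, 1], 0.5)                # d = 0, cross-type, w = 1

  # d = d0 with same label halves the distance factor
  qq <- structure_from_xyz(matrix(0, 20, 3))  # length 20 -> d0 > 0.5
  d0 <- compute_d0(20)
  mm <- structure_from_xyz(matrix(rep(c(d0, 0, 0), each = 20), 20, 3))
  sm3 <- similarity_matrix(qq, mm, rep("H", 20), rep("H", 20),
                           new_superposition(), d3, p)
  expect_equal(sm3$values[1, 1], 0.5, tolerance = 1e-12)
  expect_true(all(sm3$values >= 0 & sm3$values <= 1))
})

test_that("best segment matches exhaustive enumeration on random matrices", {
  set.seed(50)
  for (trial in 1:200) {
    nq <- sample(3:12, 1)
    nm <- sample(3:12, 1)
    vals <- matrix(0, nq, nm)
    nfill <- sample.int(nq * nm, size = ceiling(0.4 * nq * nm))
    vals[nfill] <- round(runif(length(nfill)), 3)
    mode <- sample(c("forward", "mixed"), 1)
    got <- best_segment(wrap_matrix(vals), mode = mode)
    want <- brute_best_segment(vals, mode = mode)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$score, want$score, tolerance = 1e-9)
      expect_equal(got$alpha, want$alpha)
      expect_equal(got$beta, want$beta)
      expect_equal(got$len, want$len)
      expect_equal(got$dir, want$dir)
    }
  }
})

test_that("simple segment cases resolve as expected", {
  vals <- diag(5)
  got <- best_segment(wrap_matrix(vals))
  expect_equal(c(got$alpha, got$beta, got$len), c(1L, 1L, 5L))
  expect_equal(got$score, 5)

  # two disjoint runs: the higher-scoring one wins
  vals2 <- matrix(0, 6, 6)
  vals2[cbind(1:3, 1:3)] <- c(1, 1, 0.8)     # 2.8 on the main diagonal
  vals2[4, 5] <- 1.3; vals2[5, 6] <- 1.3     # 2.6 on an offset diagonal
  got2 <- best_segment(wrap_matrix(vals2))
  expect_equal(got2$score, 2.8)
  expect_equal(got2$alpha, 1L)

  # chain breaks terminate runs
  qs <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  got3 <- best_segment(wrap_matrix(diag(5)), q_start = qs,
                       m_start = c(TRUE, rep(FALSE, 4)))
  expect_equal(got3$len, 3L)
  expect_equal(got3$alpha, 3L)
})

test_that("greedy selection reproduces the stepwise brute-force oracle", {
  set.seed(51)
  for (trial in 1:100) {
    nq <- sample(4:12, 1)
    nm <- sample(4:12, 1)
    vals <- matrix(0, nq, nm)
    nfill <- sample.int(nq * nm, size = ceiling(0.5 * nq * nm))
    vals[nfill] <- round(runif(length(nfill)), 3)
    mode <- sample(c("forward", "mixed"), 1)
    s_min <- 1.1
    # independent greedy loop over the brute-force best segment
    qb <- rep(FALSE, nq); mb <- rep(FALSE, nm)
    want <- list()
    repeat {
      seg <- brute_best_segment(vals, qb, mb, mode)
      if (is.null(seg) || seg$score < s_min) break
      want <- c(want, list(seg))
      idx <- seq_len(seg$len) - 1L
      qb[seg$alpha + idx] <- TRUE
      mb[seg$beta + (if (seg$dir == "forward") idx else -idx)] <- TRUE
    }
    got <- greedy_select(wrap_matrix(vals), s_min = s_min, mode = mode)
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_equal(got$score[k], want[[k]]$score, tolerance = 1e-9)
      expect_equal(got$alpha[k], want[[k]]$alpha)
      expect_equal(got$beta[k], want[[k]]$beta)
      expect_equal(got$len[k], want[[k]]$len)
      expect_equal(got$dir[k], want[[k]]$dir)
    }
  }
})

test_that("the minimum segment score rejects short runs and keeps carried segments", {
  expect_equal(nrow(greedy_select(wrap_matrix(matrix(0, 5, 5)))), 0L)

  # two cells of 1.0 score 2.0 < 2.2: rejected, so accepted segments span >= 3
  vals <- matrix(0, 5, 5)
  vals[1, 1] <- 1; vals[2, 2] <- 1
  expect_equal(nrow(greedy_select(wrap_matrix(vals), s_min = 2.2)), 0L)

  carried <- data.frame(alpha = 1L, beta = 1L, len = 2L, dir = "forward",
                        score = 2.0, stringsAsFactors = FALSE)
  got <- greedy_select(wrap_matrix(matrix(0, 5, 5)), carried_segments = carried)
  expect_equal(got, carried)

  # carried rows/columns block later picks
  vals2 <- matrix(0, 6, 6)
  vals2[cbind(1:6, 1:6)] <- 1
  got2 <- greedy_select(wrap_matrix(vals2), s_min = 2.2,
                        carried_segments = carried)
  expect_equal(nrow(got2), 2L)
  expect_equal(got2$alpha[2], 3L)  # rows 1-2 were blocked by the carried segment
})

test_that("stepwise alignment covers identical structures in one segment per stretch", {
  s <- make_toy_structure(random_toy_spec(61))
  lab <- assign_secondary_structure(s)
  aln <- stepwise_alignment(s, s, lab, lab, new_superposition())
  expect_equal(nrow(aln$segments), 1L)
  expect_equal(aln$segments$len, n_residues(s))
  expect_equal(aln$total_segment_score, n_residues(s), tolerance = 1e-9)
  expect_equal(aln$mtm, 1, tolerance = 1e-12)
})

test_that("looser cutoffs capture displaced elements missed at the tight one", {
  # two long strand pairs; the second sits 4 A off under the seed
  # superposition: beyond d_1 = 3.2 but within d_2 = 4.8
  q <- structure_from_xyz(rbind(ideal_strand(30),
                                ideal_strand(30, origin = c(6, 0, 0))),
                          breaks = c(1L, 31L))
  mx <- rbind(ideal_strand(30), sweep(ideal_strand(30, origin = c(6, 0, 0)), 2,
                                      c(4, 0, 0), "+"))
  m <- structure_from_xyz(mx, breaks = c(1L, 31L))
  lab <- rep("E", 60)
  p <- align_params()
  d1 <- similarity_matrix(q, m, lab, lab, new_superposition(), p$R0, p)
  expect_true(all(d1$values[31:60, 31:60] == 0))
  aln <- stepwise_alignment(q, m, lab, lab, new_superposition(), p)
  pairs <- nsalign:::alignment_pairs(aln$segments)
  expect_true(all(31:60 %in% pairs[, 1]))  # captured at a later step
  expect_true(all(1:30 %in% pairs[, 1]))
})

test_that("the modified TM score sums pair similarities over the query length", {
  s <- make_toy_structure(random_toy_spec(62))
  lab <- assign_secondary_structure(s)
  aln <- stepwise_alignment(s, s, lab, lab, new_superposition())
  expect_equal(mtm_score(aln, s, s, lab, lab), 1, tolerance = 1e-12)

  empty <- nsalign:::new_alignment(
    data.frame(alpha = integer(0), beta = integer(0), len = integer(0),
               dir = character(0), score = numeric(0)), new_superposition())
  expect_equal(mtm_score(empty, s, s, lab, lab), 0)

  # hand-built three-pair alignment: known M values divided by N = 10
  p <- align_params()
  d0 <- compute_d0(10)
  qx <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0), matrix(99, 7, 3))
  mx <- qx
  mx[2, 3] <- d0    # M = 0.5 (same label)
  q10 <- structure_from_xyz(qx)
  m10 <- structure_from_xyz(mx)
  labq <- c("H", "H", "H", rep("C", 7))
  labm <- c("H", "H", "E", rep("C", 7))  # third pair cross-type: M = 0.5
  aln3 <- nsalign:::new_alignment(
    data.frame(alpha = 1L, beta = 1L, len = 3L, dir = "forward", score = 2,
               stringsAsFactors = FALSE), new_superposition())
  expect_equal(mtm_score(aln3, q10, m10, labq, labm, p), 0.2, tolerance = 1e-9)
})

test_that("refinement never degrades the score and converges quickly", {
  s <- make_toy_structure(random_toy_spec(63))
  lab <- assign_secondary_structure(s)
  ini <- stepwise_alignment(s, s, lab, lab, new_superposition())
  ref <- refine_alignment(s, s, lab, lab, ini)
  expect_equal(ref$mtm, 1, tolerance = 1e-12)
  expect_equal(ref$iterations, 1L)

  # perturbed seed: ~1 A / 5 degrees off the optimum
  ang <- 5 * pi / 180
  rot <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  seed <- new_superposition(rot, c(1, 0, 0))
  ini2 <- stepwise_alignment(s, s, lab, lab, seed)
  ref2 <- refine_alignment(s, s, lab, lab, ini2)
  expect_gte(ref2$mtm, ini2$mtm)
  expect_lte(ref2$iterations, 30L)
  expect_gt(ref2$mtm, 0.99)
})

test_that("refinement converges within the cap on many toy pairs", {
  for (sd in 1:15) {
    q <- make_toy_structure(random_toy_spec(sd))
    m <- make_toy_structure(random_toy_spec(sd + 500))
    res <- tryCatch(align_pair(q, m), nsalign_no_sse = function(e) NULL)
    if (is.null(res) || res$status != "ok") next
    for (a in res$alignments) expect_lte(a$iterations, 30L)
  }
})

test_that("full alignment of a structure with itself is exact", {
  for (sd in c(71, 72, 73)) {
    s <- make_toy_structure(random_toy_spec(sd))
    res <- align_pair(s, s)
    expect_equal(res$status, "ok")
    expect_equal(q_score(res$best, identity_pairs(n_residues(s))), 100)
    expect_lt(res$stats$rmsd, 1e-6)
    expect_gte(res$best$mtm, 0.99)
  }
})

test_that("alignment output is invariant under rigid transforms of one input", {
  set.seed(80)
  s <- make_toy_structure(random_toy_spec(74))
  m <- make_toy_structure(random_toy_spec(75))
  base <- align_pair(s, m)
  key0 <- nsalign:::segment_set_key(base$best$segments)
  for (trial in 1:3) {
    moved <- transform_structure(m, random_rigid())
    res <- align_pair(s, moved)
    expect_equal(nsalign:::segment_set_key(res$best$segments), key0)
  }
})

test_that("structural guarantees hold on every emitted alignment", {
  for (sd in c(81, 82, 83)) {
    q <- make_toy_structure(random_toy_spec(sd))
    m <- make_toy_structure(random_toy_spec(sd + 600))
    res <- tryCatch(align_pair(q, m), nsalign_no_sse = function(e) NULL)
    if (is.null(res) || res$status != "ok") next
    for (a in res$alignments) {
      pairs <- nsalign:::alignment_pairs(a$segments)
      # one-to-one
      expect_false(any(duplicated(pairs[, 1])))
      expect_false(any(duplicated(pairs[, 2])))
      # no 1-2 residue fragments, and forward mode means forward only
      expect_true(all(a$segments$len >= 3L))
      expect_true(all(a$segments$dir == "forward"))
      # best-of-seeds contract
      expect_gte(res$best$mtm, a$mtm - 1e-12)
    }
    st <- res$stats
    expect_equal(st$n_ali_percent, st$n_ali_prime_percent)
  }
})

test_that("type-disjoint pairs yield an empty result and tiny inputs a no-SSE error", {
  helixy <- make_toy_structure(list(elements = list(
    list(type = "H", length = 12, origin = c(0, 0, 0), axis = c(0, 0, 1)),
    list(type = "H", length = 12, origin = c(10, 0, 16.5), axis = c(0, 0, -1))),
    loop_length = 4, seed = 3))
  strandy <- make_toy_structure(list(elements = list(
    list(type = "E", length = 8, origin = c(0, 0, 0), axis = c(0, 0, 1)),
    list(type = "E", length = 8, origin = c(5, 0, 23.1), axis = c(0, 0, -1))),
    loop_length = 2, seed = 4))
  res <- align_pair(helixy, strandy)
  expect_equal(res$status, "empty")

  tiny <- structure_from_xyz(ideal_strand(4))
  expect_error(align_pair(tiny, strandy), class = "nsalign_no_sse")
})

test_that("mixed mode finds reverse fragments that forward mode cannot", {
  specA <- list(elements = list(
    list(type = "H", length = 14, origin = c(0, 0, 0), axis = c(0, 0, 1)),
    list(type = "H", length = 14, origin = c(10, 0, 0), axis = c(0, 0, 1))),
    loop_length = 6, seed = 5)
  A <- make_toy_structure(specA)
  nh <- 14L; nl <- 6L
  idx <- c(seq_len(nh + nl), rev((nh + nl + 1L):(2L * nh + nl)))
  at <- A$atoms[idx, ]
  at$resno <- seq_len(nrow(at))
  rownames(at) <- NULL
  B <- new_protein_ca(at, label = "revhelix", breaks = c(1L, nh + nl + 1L))

  fw <- align_pair(A, B, align_params(mode = "forward"))
  mx <- align_pair(A, B, align_params(mode = "mixed"))
  expect_false(any(fw$best$segments$dir == "reverse"))
  expect_true(any(mx$best$segments$dir == "reverse"))
  expect_gt(mx$best$mtm, fw$best$mtm)
})
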