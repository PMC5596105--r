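
test_that("tag mapping equals a brute-force Hamming scan", {
  withr::with_seed(33, {
    locus <- random_seq(500)
    tags <- c(replicate(10, random_seq(21)),
              # planted with 0-3 mismatches
              vapply(1:10, function(i) {
                s <- sample(460, 1)
                t <- substr(locus, s + 1, s + 21)
                for (p in sample(21, sample(0:3, 1))) {
                  substr(t, p, p) <- sample(c("A", "C", "G", "T"), 1)
                }
                t
              }, ""))
    loci <- c(L1 = locus)
    got <- map_tags(tags, loci)
    for (tg in unique(tags)) {
      want <- brute_map(tg, loci)
      g <- got[got$sequence == tg, c("start", "strand", "n_mismatches")]
      if (is.null(want)) {
        expect_equal(nrow(g), 0, info = tg)
      } else {
        g <- g[order(g$start, g$strand), ]
        want <- want[order(want$start, want$strand), ]
        expect_equal(g$start, want$start, info = tg)
        expect_equal(g$strand, want$strand, info = tg)
        expect_equal(g$n_mismatches, want$n_mismatches, info = tg)
      }
    }
  })
})

test_that("exact substrings map once; 3 mismatches do not map", {
  withr::with_seed(1, {
    locus <- c(L = random_seq(200))
    tag <- substr(locus[[1]], 51, 71)
    m <- map_tags(tag, locus)
    expect_equal(nrow(m), 1)
    expect_equal(m$n_mismatches, 0L)
    expect_equal(m$start, 50L)
    bad <- tag
    for (p in c(3, 10, 17)) substr(bad, p, p) <-
        setdiff(c("A", "C", "G", "T"), substr(bad, p, p))[1]
    expect_equal(nrow(map_tags(bad, locus)), 0)
  })
})

test_that("locus calling applies the 100-read threshold at the boundary", {
  withr::with_seed(2, {
    locus <- c(L = random_seq(1200))
    t1 <- substr(locus[[1]], 101, 121)   # stack 1
    t2 <- substr(locus[[1]], 701, 721)   # stack 2, 500 nt away
    tags <- tibble::tibble(sequence = c(t1, t2), total = c(99L, 100L))
    m <- map_tags(tags, locus)
    called <- call_loci(m, min_reads = 100)
    expect_equal(nrow(called), 1)
    expect_equal(called$stack_start, 700L)
    tags2 <- tibble::tibble(sequence = c(t1, t2), total = c(100L, 100L))
    called2 <- call_loci(map_tags(tags2, locus), min_reads = 100)
    expect_equal(nrow(called2), 2)
    # lowering the threshold never removes an accepted locus (monotone)
    called3 <- call_loci(map_tags(tags2, locus), min_reads = 50)
    expect_true(all(paste(called2$locus_id, called2$stack_start) %in%
                      paste(called3$locus_id, called3$stack_start)))
  })
})

test_that("windows are centered, grown and truncated as specified", {
  withr::with_seed(3, {
    locus <- random_seq(400)
    w <- extract_window(locus, 200, 221, 100)
    expect_equal(w$end - w$start, 2 * 100 + 21)
    expect_false(w$truncated)
    # modal tag 30 nt from the start: left side truncated and flagged
    w2 <- extract_window(locus, 30, 51, 80)
    expect_equal(w2$start, 0L)
    expect_true(w2$truncated)
    sched <- sporomir:::window_schedule(21, 80, 300, 1000, 20)
    expect_equal(sched[1], 80)
    expect_true(all(diff(sched) > 0))
    expect_true(all(2 * sched + 21 <= 1000))
    expect_gt(max(2 * sched + 21), 900)
  })
})

test_that("the fold equals brute-force enumeration on short windows", {
  expect_equal(fold_hairpin("GGGAAACCC")$structure, "(((...)))")
  expect_equal(fold_hairpin("GGGAAACCC")$score, 9)
  expect_equal(fold_hairpin("AAAAAAAAA")$structure, ".........")
  expect_equal(fold_hairpin("AAAAAAAAA")$score, 0)
  withr::with_seed(4, {
    for (i in 1:40) {
      s <- random_seq(sample(5:14, 1))
      expect_equal(fold_hairpin(s)$score, brute_fold_score(s), info = s)
    }
  })
})

test_that("folded structures are balanced, nested and loop-limited", {
  withr::with_seed(5, {
    for (i in 1:10) {
      s <- random_seq(sample(30:120, 1))
      hp <- fold_hairpin(s)
      pr <- hp$pairs
      if (nrow(pr) == 0) next
      expect_true(all(pr[, 2] - pr[, 1] >= 4))
      # nestedness: no crossing pairs
      if (nrow(pr) > 1) {
        for (a in seq_len(nrow(pr) - 1)) {
          for (b in (a + 1):nrow(pr)) {
            i1 <- pr[a, 1]; j1 <- pr[a, 2]; i2 <- pr[b, 1]; j2 <- pr[b, 2]
            crossing <- (i1 < i2 && i2 < j1 && j1 < j2) ||
              (i2 < i1 && i1 < j2 && j2 < j1)
            expect_false(crossing)
          }
        }
      }
      expect_equal(sum(strsplit(hp$structure, "")[[1]] == "("), nrow(pr))
    }
  })
})

test_that("duplex validation passes designed hairpins and rejects broken ones", {
  withr::with_seed(6, {
    g <- random_seq(21)
    for (n_mm in c(0, 3)) {
      hw <- make_hairpin_window(g, n_mm)
      hp <- fold_hairpin(hw$seq)
      v <- validate_duplex(hp, hw$guide_start, hw$guide_end)
      expect_true(v$pass, info = paste("mm", n_mm))
      expect_equal(v$arm, "5p")
    }
    hw6 <- make_hairpin_window(g, 6)
    v6 <- validate_duplex(fold_hairpin(hw6$seq), hw6$guide_start,
                          hw6$guide_end)
    expect_false(v6$pass)
    # a guide centered on the terminal loop fails
    hw <- make_hairpin_window(g, 0)
    mid <- floor((hw$guide_end + hw$star_start) / 2)
    v_loop <- validate_duplex(fold_hairpin(hw$seq), mid - 10, mid + 11)
    expect_false(v_loop$pass)
    expect_match(v_loop$reason, "loop|paired|sides")
  })
})

test_that("star assignment honours counts and the 6-nt shift limit", {
  withr::with_seed(7, {
    g <- random_seq(21)
    hw <- make_hairpin_window(g, 0, flank = 20)
    hp <- fold_hairpin(hw$seq)
    v <- validate_duplex(hp, hw$guide_start, hw$guide_end)
    expect_true(v$pass)
    exp_span <- sporomir:::expected_star_span(v)
    # a tag at displacement 6 is accepted, 7 is rejected
    for (d in c(6L, 7L)) {
      pl <- tibble::tibble(
        sequence = substr(hp$seq, exp_span[1] + d + 1, exp_span[2] + d),
        wstart = exp_span[1] + d, wend = exp_span[2] + d, total = 120L)
      star <- assign_guide_star(pl, hp, v, hw$guide_start, hw$guide_end,
                                star_shift = 6)
      if (d == 6L) {
        expect_equal(star$star_count, 120L)
        expect_equal(star$star_shift_used, 6L)
      } else {
        expect_equal(star$star_count, 0)
        expect_true(is.na(star$star_shift_used))
      }
    }
    # higher-count opposite-arm tag wins; guide stays the guide upstream
    pl2 <- tibble::tibble(
      sequence = c(substr(hp$seq, hw$star_start + 1, hw$star_end),
                   substr(hp$seq, hw$star_start + 3, hw$star_end)),
      wstart = c(hw$star_start, hw$star_start + 2),
      wend = c(hw$star_end, hw$star_end), total = c(500L, 120L))
    star2 <- assign_guide_star(pl2, hp, v, hw$guide_start, hw$guide_end)
    expect_equal(star2$star_count, 500L)
    # no opposite-arm tag: theoretical star with count 0
    star3 <- assign_guide_star(pl2[0, ], hp, v, hw$guide_start, hw$guide_end)
    expect_equal(star3$star_count, 0)
    expect_gt(nchar(star3$star_seq), 15)
  })
})

test_that("deduplication routes conserved guides and collapses shared guides", {
  cand <- tibble::tibble(
    locus_id = c("tx1", "tx2", "tx3"), strand = "+",
    stack_start = 0L, stack_end = 100L, total_reads = 500,
    n_distinct_tags = 3L, window_start = 0L, window_end = 100L,
    flank = 80L, truncated = FALSE,
    guide_seq = c("AAACCCGGGTTTAAACCCGGG", "AAACCCGGGTTTAAACCCGGG",
                  "TTTGGGCCCAAATTTGGGCCC"),
    guide_arm = c("5p", "5p", "3p"), guide_count = c(400L, 400L, 300L),
    star_seq = "x", star_count = 10, star_shift_used = 0L,
    n_paired = 18L, n_unpaired = 3L, n_bulged = 1L,
    precursor_seq = "x", structure = "x", score = 10L)
  hits <- tibble::tibble(sequence = "TTTGGGCCCAAATTTGGGCCC",
                         ref_id = "ref-a", family = "miR166",
                         n_sub = 0L, offset_5p = 0L, offset_3p = 0L)
  out <- dedupe_and_name(cand, hits)
  expect_equal(nrow(out$novel), 1)
  expect_equal(out$novel$n_precursors, 2L)
  expect_match(out$novel$mirna_id, "^Pab-miRn0001_5p$")
  expect_equal(out$conserved_candidates$family, "miR166")
  expect_false(any(out$novel$sequence %in% hits$sequence))
})
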