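d48 <- oligo_d48()

test_that("the duplex template anneals fully with its complement", {
  a <- anneal(list(d48, oligo("D-48c", revcomp(d48$sequence))))
  expect_identical(classify_structure(a), "ds")
  expect_identical(sum(a$segments$length), 48L)
})

test_that("the printed overhang construct gives a 20-bp duplex with a 28-nt tail", {
  a <- anneal(list(d48, oligo("J24.rgt", "ACTCAACTGCACTCTAGACT")))
  expect_identical(classify_structure(a), "ov")
  expect_identical(max(a$segments$length), 20L)
  # the labeled strand keeps a single 28-nt single-stranded 3' tail
  ps <- a$pairing$strand[[1]]
  expect_identical(sum(ps == 0L), 28L)
  expect_true(all(which(ps == 0L) == 21:48))
})

test_that("bulge constructs carry their unpaired adenine count in the label", {
  comp <- revcomp(d48$sequence)
  for (m in c(1L, 3L, 7L)) {
    bulged <- paste0(substr(comp, 1, 24), strrep("A", m),
                     substr(comp, 25, 48))
    a <- anneal(list(d48, oligo("bulge", bulged)))
    expect_identical(classify_structure(a), paste0("A", m))
  }
})

test_that("nick, fork, junction, incomplete junction and invasion classify", {
  P <- substr(d48$sequence, 1, 24); Q <- substr(d48$sequence, 25, 48)
  arm_r <- "GGATCAGTTCAGGATCCATTGGAC"
  arm_s <- "CCTTAGTTCCGGTTAACGGTTCAC"
  nick <- anneal(list(d48, oligo("L", revcomp(P)), oligo("R", revcomp(Q))))
  expect_identical(classify_structure(nick), "n")
  fork <- anneal(list(d48, oligo("F", paste0("GGATGGTTGGTAGGATTGGATTGG",
                                             revcomp(P)))))
  expect_identical(classify_structure(fork), "fork")
  s2 <- oligo("s2", paste0(revcomp(Q), arm_r))
  s3 <- oligo("s3", paste0(revcomp(arm_r), arm_s))
  s4 <- oligo("s4", paste0(revcomp(arm_s), revcomp(P)))
  expect_identical(classify_structure(anneal(list(d48, s2, s3, s4))), "J")
  expect_identical(classify_structure(anneal(list(d48, s2, s4))), "iJ")
  inv <- anneal(list(d48, oligo("F36", revcomp(substr(d48$sequence, 1, 36))),
                     oligo("V24", revcomp(Q))))
  expect_identical(classify_structure(inv), "inv")
})

test_that("non-complementary oligo pairs refuse to assemble", {
  expect_error(anneal(list(oligo("x", "ACGTACGTACGTACGTACGT"),
                           oligo("y", "TTTTGGGGTTTTGGGGTTTT"))),
               "no stable assembly")
})

test_that("assembly is invariant to oligo input order", {
  P <- substr(d48$sequence, 1, 24); Q <- substr(d48$sequence, 25, 48)
  s2 <- oligo("s2", paste0(revcomp(Q), "GGATCAGTTCAGGATCCATTGGAC"))
  s4 <- oligo("s4", paste0(revcomp("GGATCAGTTCAGGATCCATTGGAC"), revcomp(P)))
  sets <- list(list(d48, s2, s4), list(s2, d48, s4), list(s4, s2, d48),
               list(s2, s4, d48))
  refs <- lapply(sets, anneal)
  for (r in refs[-1]) {
    expect_identical(r$segments, refs[[1]]$segments)
    expect_identical(classify_structure(r), classify_structure(refs[[1]]))
  }
})

test_that("random non-self-complementary duplexes always classify as ds", {
  set.seed(99)
  for (i in 1:100) {
    len <- sample(20:48, 1)
    s <- random_oligo_seq(len)
    a <- anneal(list(oligo("t", s, labeled = TRUE), oligo("b", revcomp(s))))
    expect_identical(classify_structure(a), "ds")
  }
})

test_that("every paired segment is exactly antiparallel complementary", {
  comp_of <- c(A = "T", C = "G", G = "C", T = "A")
  check_assembly <- function(a) {
    for (i in seq_len(nrow(a$strands))) {
      si <- strsplit(a$strands$sequence[i], "")[[1]]
      for (pos in seq_along(si)) {
        j <- a$pairing$strand[[i]][pos]
        if (j != 0L) {
          q <- a$pairing$base[[i]][pos]
          sj <- strsplit(a$strands$sequence[j], "")[[1]]
          expect_identical(comp_of[[si[pos]]], sj[q])
          # reciprocity
          expect_identical(a$pairing$strand[[j]][q], i)
          expect_identical(a$pairing$base[[j]][q], pos)
        }
      }
    }
  }
  check_assembly(anneal(list(d48, oligo("c", revcomp(d48$sequence)))))
  check_assembly(anneal(list(d48, oligo("J24.rgt", "ACTCAACTGCACTCTAGACT"))))
  comp <- revcomp(d48$sequence)
  check_assembly(anneal(list(d48, oligo("b", paste0(substr(comp, 1, 24),
                                                    "AAA",
                                                    substr(comp, 25, 48))))))
})

test_that("the truncation series produces the printed duplex lengths", {
  ts <- truncation_series(d48, 21:36)
  expect_length(ts, 16L)
  lens <- vapply(ts, function(a) sum(a$segments$length), integer(1))
  expect_identical(unname(lens), 21:36)
  expect_true(all(vapply(ts, classify_structure, character(1)) == "ds"))
  expect_error(truncation_series(d48, c(4, 20)), "below 8")
  expect_error(truncation_series(d48, 50), "exceed")
})
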