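test_that("proximal anchoring finds the flank and flags ambiguity", {
  ref <- shared_ref()
  h <- simulate_terminal_healing(ref, del_size = 5000L, copies = 6L, mh = 0L,
                                 seed = 61L)
  a <- anchor_proximal(h$record$seq, ref)
  expect_identical(a$seq_name, "chrT")
  expect_identical(a$q_start, 0L)
  # the anchor reaches (at least) the breakpoint
  expect_gte(a$ref_end, h$truth$breakpoints[1])
  expect_true(a$unique)
  expect_gte(a$identity, 0.95)

  # a read wholly inside the near-identical paralog pair is ambiguous
  pb <- ref$features[ref$features$kind == "paralog_block" &
                       ref$features$seq_name == "chrT", ]
  pread <- substr(ref$sequences$chrT, pb$start + 301L, pb$start + 600L)
  ap <- anchor_proximal(pread, ref)
  expect_false(ap$unique)
  expect_gte(ap$ambiguity_count, 2L)

  expect_error(anchor_proximal(substr(pread, 1, 30), ref), "60 bp")
  expect_error(anchor_proximal(random_seq(100, 99), ref), "unanchored")
})

test_that("junction microhomology equals the exhaustive oracle on simulations", {
  ref <- shared_ref()
  for (s in 1:25) {
    mh <- s %% 6L
    sim <- simulate_interstitial_nhej(ref, del_size = 3000L, mh = mh,
                                      seed = 700 + s)
    cl <- call_junction(sim$record$seq, ref)
    tr <- sim$truth
    want <- oracle_mh(ref$sequences$chrT, tr$breakpoints[1],
                      ref$sequences$chrT, tr$breakpoints[2])
    expect_identical(cl$microhomology_len, as.integer(want))
    expect_identical(want, as.integer(mh))
  }
})

test_that("untemplated inserts are recovered verbatim and exclusively of mh", {
  ref <- shared_ref()
  sim <- simulate_interstitial_nhej(ref, del_size = 3000L,
                                    insert = "TTGGACCATG", seed = 71L)
  cl <- call_junction(sim$record$seq, ref)
  expect_identical(cl$untemplated_insert, "TTGGACCATG")
  expect_identical(cl$microhomology_len, 0L)

  blunt <- simulate_interstitial_nhej(ref, del_size = 3000L, mh = 0L,
                                      seed = 72L)
  clb <- call_junction(blunt$record$seq, ref)
  expect_identical(clb$untemplated_insert, "")

  # breakpoint interval width is microhomology + 1
  for (s in 73:78) {
    sim <- simulate_interstitial_nhej(ref, del_size = 3000L, mh = s %% 6L,
                                      seed = s)
    cl <- call_junction(sim$record$seq, ref)
    expect_identical(cl$breakpoint_interval$end - cl$breakpoint_interval$start,
                     cl$microhomology_len + 1L)
  }
})

test_that("templated-insert search respects min_len and orientation", {
  expect_null(find_inverted_template("ACGTACGT", random_seq(500, 81),
                                     min_len = 15L))
  del <- random_seq(400, 82)
  tmpl <- substr(del, 101, 124)
  hit <- find_inverted_template(revcomp(tmpl), del)
  expect_identical(hit$orientation, "reverse_complement")
  expect_identical(hit$src_start, 100L)
  expect_identical(hit$len, 24L)
  fhit <- find_inverted_template(tmpl, del)
  expect_identical(fhit$orientation, "forward")
  expect_identical(fhit$src_start, 100L)
})

test_that("distal assignment follows the telomere/TAR/genomic priority", {
  ref <- shared_ref()
  heal <- simulate_terminal_healing(ref, del_size = 5000L, copies = 8L,
                                    seed = 85L)
  expect_identical(call_junction(heal$record$seq, ref)$distal$kind,
                   "telomere_array")
  cap <- simulate_telomere_capture(ref, del_size = 6000L, source = "tar_block",
                                   seed = 86L, mut_rate = 0)
  expect_identical(call_junction(cap$record$seq, ref)$distal$kind, "tar_block")
  tx <- simulate_translocation_junction(ref, mh = 0L, seed = 87L)
  expect_identical(call_junction(tx$record$seq, ref)$distal$kind,
                   "genomic_locus")
  # a junk suffix cannot be assigned
  junk <- paste0(substr(ref$sequences$chrT, 50001, 50200), random_seq(80, 88))
  expect_identical(call_junction(junk, ref)$distal$kind, "unassigned")
  # ring junction into a repeat decoy is flagged ambiguous
  rd <- simulate_ring_junction(ref, q_del_size = 6000L,
                               distal_in_decoy = TRUE, seed = 89L)
  cl <- call_junction(rd$record$seq, ref)
  expect_false(cl$distal$anchor$unique)
  expect_gte(cl$distal$ambiguity_count, 3L)
})

test_that("call_junction is total and idempotent", {
  ref <- shared_ref()
  bad <- call_junction(random_seq(120, 91), ref, read_id = "junk")
  expect_identical(bad$error, "unanchored read")
  expect_identical(bad$distal$kind, "unassigned")

  sim <- simulate_fostes(ref, template_len = 26L, mh_prox = 3L, mh_dist = 2L,
                         seed = 92L)
  c1 <- call_junction(sim$record$seq, ref, read_id = "x")
  c2 <- call_junction(sim$record$seq, ref, read_id = "x")
  expect_identical(c1, c2)

  td <- withr::local_tempdir()
  write_calls_jsonl(list(c1, bad), file.path(td, "calls.jsonl"))
  lines <- readLines(file.path(td, "calls.jsonl"))
  expect_length(lines, 2L)
  parsed <- jsonlite::fromJSON(lines[1])
  expect_identical(parsed$template_insert$orientation, "reverse_complement")
})
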