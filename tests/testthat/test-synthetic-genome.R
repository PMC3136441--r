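test_that("reference construction is deterministic and well-formed", {
  ref <- shared_ref()
  expect_s3_class(ref, "reference_genome")
  expect_equal(nchar(ref$sequences$chrT), 200000L)
  # terminal telomere array by construction
  telo <- ref$features[ref$features$kind == "telomere_array" &
                         ref$features$seq_name == "chrT", ]
  expect_equal(telo$end, 200000L)
  expect_equal(substr(ref$sequences$chrT, 200000L - 5L, 200000L), "GGTTAG")
  expect_equal(telo$end - telo$start, 300L)
  # features lie within their sequences
  lens <- vapply(ref$sequences, nchar, integer(1))
  expect_true(all(ref$features$start < ref$features$end))
  expect_true(all(ref$features$end <= lens[ref$features$seq_name]))
  # identical (config, seed) -> identical bytes
  ref2 <- build_reference(seed = 1L)
  expect_identical(ref$sequences, ref2$sequences)
  expect_identical(ref$features, ref2$features)
  # background GC close to target
  gc <- mean(chars(ref$sequences$chrT) %in% c("G", "C"))
  expect_lt(abs(gc - 0.48), 0.05)
})

test_that("reference construction rejects degenerate configurations", {
  expect_error(build_reference(sim_config(telomere_units = 0L)),
               "telomere_units")
  expect_error(build_reference(sim_config(chr_len = 50000L)), "10x")
})

test_that("terminal healing reads carry the requested junction signature", {
  ref <- shared_ref()
  h <- simulate_terminal_healing(ref, del_size = 5000L, copies = 6L, mh = 0L,
                                 seed = 11L)
  expect_true(endsWith(h$record$seq, strrep("GGTTAG", 6L)))
  expect_identical(h$truth$mechanism, "telomere_healing")
  expect_gte(nchar(h$record$seq), 150L + 36L)

  # untemplated insert is analyzer-visible verbatim
  hi <- simulate_terminal_healing(ref, del_size = 5000L, copies = 5L,
                                  insert = "GATTACAGATTACA", seed = 12L)
  expect_identical(hi$truth$untemplated_insertion, "GATTACAGATTACA")
  expect_true(grepl(paste0("GATTACAGATTACA", strrep("GGTTAG", 5L), "$"),
                    hi$record$seq))

  # engineered fusion microhomology equals the k-loop oracle on the read
  h5 <- simulate_terminal_healing(ref, del_size = 5000L, copies = 4L, mh = 5L,
                                  seed = 13L)
  flank <- sub("(GGTTAG)+$", "", h5$record$seq)
  expect_identical(oracle_fusion_mh(flank), 5L)

  expect_error(simulate_terminal_healing(ref, del_size = 2 * 200000L,
                                         seed = 1L), "del_size")
  expect_error(simulate_terminal_healing(ref, mh = 6L, seed = 1L), "0..5")
})

test_that("telomere capture copies the donor block", {
  ref <- shared_ref()
  cap <- simulate_telomere_capture(ref, del_size = 6000L, source = "tar_block",
                                   seed = 21L, mut_rate = 0)
  src <- cap$truth$source_interval
  tar <- ref$features[ref$features$kind == "tar_block" &
                        ref$features$seq_name == "chrT", ]
  expect_true(src[1] >= tar$start && src[2] <= tar$end)
  donor <- substr(ref$sequences$chrT, src[1] + 1L, src[2])
  expect_true(grepl(donor, cap$record$seq, fixed = TRUE))

  capf <- simulate_telomere_capture(ref, del_size = 6000L,
                                    source = "foreign_subtelomere",
                                    seed = 22L, mut_rate = 0.01)
  expect_identical(capf$truth$source_seq, "chrB")
  src <- capf$truth$source_interval
  donor <- substr(ref$sequences$chrB, src[1] + 1L, src[2])
  emitted <- substr(capf$record$seq, 201L, 200L + nchar(donor))
  ident <- mean(chars(donor) == chars(emitted))
  expect_gte(ident, 0.95)
})

test_that("interstitial NHEJ junctions carry engineered microhomology", {
  ref <- shared_ref()
  bl <- simulate_interstitial_nhej(ref, del_size = 4000L, mh = 0L, seed = 31L)
  tr <- bl$truth
  expect_identical(oracle_mh(ref$sequences$chrT, tr$breakpoints[1],
                             ref$sequences$chrT, tr$breakpoints[2]), 0L)
  m5 <- simulate_interstitial_nhej(ref, del_size = 4000L, mh = 5L, seed = 32L)
  tr <- m5$truth
  expect_identical(oracle_mh(ref$sequences$chrT, tr$breakpoints[1],
                             ref$sequences$chrT, tr$breakpoints[2]), 5L)
  ins <- simulate_interstitial_nhej(ref, del_size = 4000L,
                                    insert = "TTGACCGGTA", seed = 33L)
  expect_identical(ins$truth$untemplated_insertion, "TTGACCGGTA")
  expect_error(simulate_interstitial_nhej(ref, mh = 3L, insert = "AA",
                                          seed = 1L), "mutually exclusive")
})

test_that("FoSTeS truth template is recoverable by brute-force scan", {
  ref <- shared_ref()
  fo <- simulate_fostes(ref, template_len = 24L, mh_prox = 4L, mh_dist = 2L,
                        seed = 41L)
  tr <- fo$truth
  t1 <- tr$template_insert$interval[1]; t2 <- tr$template_insert$interval[2]
  template_rc <- revcomp(substr(ref$sequences$chrT, t1 + 1L, t2))
  expect_true(grepl(template_rc, fo$record$seq, fixed = TRUE))
  # template drawn from the interior of the deleted interval
  expect_gt(t1, tr$breakpoints[1])
  expect_lt(t2, tr$breakpoints[2])
  # orientation flag honoured
  fof <- simulate_fostes(ref, template_len = 24L, mh_prox = 2L, mh_dist = 1L,
                         orientation = "forward", seed = 42L)
  tt <- fof$truth$template_insert
  expect_identical(tt$orientation, "forward")
  expect_true(grepl(substr(ref$sequences$chrT, tt$interval[1] + 1L,
                           tt$interval[2]), fof$record$seq, fixed = TRUE))
  # zero-length template degenerates to plain NHEJ
  nh <- simulate_fostes(ref, del_size = 4000L, template_len = 0L, seed = 43L)
  expect_identical(nh$truth$mechanism, "nhej_interstitial")
})

test_that("ring and translocation junctions join the expected loci", {
  ref <- shared_ref()
  ri <- simulate_ring_junction(ref, q_del_size = 6000L, mh = 2L, seed = 51L)
  expect_identical(ri$truth$mechanism, "ring_junction")
  expect_lt(ri$truth$breakpoints[2], ri$truth$breakpoints[1])
  expect_false(grepl("GGTTAGGGTTAGGGTTAG", ri$record$seq, fixed = TRUE))
  expect_error(simulate_ring_junction(ref, q_del_size = 10 * 200000L,
                                      seed = 1L), "q_del_size")

  rd <- simulate_ring_junction(ref, q_del_size = 6000L, distal_in_decoy = TRUE,
                               seed = 52L)
  expect_true(rd$truth$ambiguous_distal)

  tl <- simulate_translocation_junction(ref, mh = 4L, seed = 53L)
  expect_identical(oracle_mh(ref$sequences$chrT, tl$truth$breakpoints[1],
                             ref$sequences$chrB, tl$truth$breakpoints[2]), 4L)
  tl5 <- simulate_translocation_junction(ref, mh = 5L, seed = 54L)
  expect_identical(oracle_mh(ref$sequences$chrT, tl5$truth$breakpoints[1],
                             ref$sequences$chrB, tl5$truth$breakpoints[2]), 5L)
})

test_that("cohort simulation is reproducible and respects the mixture", {
  ref <- shared_ref()
  sim <- simulate_cohort(ref, n = 30L, seed = 9L, capture_mut_rate = 0)
  expect_length(sim$reads, 30L)
  expect_length(sim$truth, 30L)
  expect_identical(names(sim$reads), names(sim$truth))
  sim2 <- simulate_cohort(ref, n = 30L, seed = 9L, capture_mut_rate = 0)
  expect_identical(sim$reads, sim2$reads)

  allheal <- simulate_cohort(ref, n = 12L,
                             mixture = c(telomere_healing = 1), seed = 10L)
  mech <- vapply(allheal$truth, `[[`, character(1), "mechanism")
  expect_true(all(mech == "telomere_healing"))

  # every read carries >= 150 bp of proximal flank
  expect_true(all(nchar(sim$reads) >= 150L))
})

test_that("simulation round-trips through FASTA/BED/JSONL files", {
  ref <- shared_ref()
  td <- withr::local_tempdir()
  write_reference(ref, fasta = file.path(td, "ref.fa"),
                  bed = file.path(td, "ref.bed"))
  ref2 <- read_reference(file.path(td, "ref.fa"), file.path(td, "ref.bed"))
  expect_identical(ref2$sequences$chrT, ref$sequences$chrT)
  expect_identical(ref2$features$start, ref$features$start)

  sim <- simulate_cohort(ref, n = 5L, seed = 4L, capture_mut_rate = 0)
  paths <- write_simulation(sim, file.path(td, "sim"))
  reads <- Biostrings::readDNAStringSet(paths[["reads"]])
  expect_identical(unname(as.character(reads)), unname(sim$reads))
  expect_identical(names(reads), names(sim$reads))
  truth_lines <- readLines(paths[["truth"]])
  expect_length(truth_lines, 5L)
  tr1 <- jsonlite::fromJSON(truth_lines[1])
  expect_identical(tr1$id, names(sim$truth)[1])
})
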