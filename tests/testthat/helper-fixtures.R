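# Shared fixtures, built once per test run and cached.  The default study
# fixture is one toy genome with four libraries (two males, one
# one-active-X female, one two-active-X female) pushed through the whole
# pipeline.

.fix <- new.env(parent = emptyenv())

fix_config <- function() {
  if (is.null(.fix$config)) .fix$config <- sim_config(seed = 1L)
  .fix$config
}

fix_genome <- function() {
  if (is.null(.fix$genome)) .fix$genome <- generate_toy_genome(fix_config())
  .fix$genome
}

fix_libraries <- function() {
  if (is.null(.fix$libs)) {
    g <- fix_genome()
    .fix$libs <- list(
      `IVF-M1` = simulate_library(g, "IVF-M1", "male"),
      `IVF-M2` = simulate_library(g, "IVF-M2", "male"),
      `Pa2.2` = simulate_library(g, "Pa2.2", "one_active_X"),
      `Pa3` = simulate_library(g, "Pa3", "two_active_X"))
  }
  .fix$libs
}

fix_pipeline <- function() {
  if (is.null(.fix$pipe)) {
    .fix$pipe <- run_pipeline(fix_genome(), fix_libraries(),
                              call_novel = TRUE,
                              xci_test = c("Pa2.2", "Pa3"),
                              xci_reference = c("IVF-M1", "IVF-M2"))
  }
  .fix$pipe
}

# A tiny hand-made library wrapped as a sim_library, for constructed
# cleaning fixtures.
manual_library <- function(reads, quals, sample = "manual") {
  structure(list(sample = sample, reads = reads, quals = quals,
                 truth_counts = NULL, class_counts = NULL),
            class = "sim_library")
}

phred_string <- function(q, len) strrep(rawToChar(as.raw(q + 33L)), len)
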