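# Shared fixtures, built once per test run and memoized. All synthetic,
# generated in code; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# a small intact cluster shared by annotation/orthology/report tests
tiny_cluster <- function() {
  fixture("tiny", function() {
    # array copies more diverged (8%) than the 5% sister-species split, so
    # per-copy orthology is identifiable
    generate_cluster(cluster_config(seed = 101L, n_sedc = 4L, n_sftp = 2L,
                                    lce_array_size = 3L,
                                    lce_divergence = 0.08, lesion_rate = 0))
  })
}

tiny_sister <- function() {
  fixture("tiny_sister", function() {
    sister_cluster(tiny_cluster(), divergence = 0.05, lesion_rate = 0,
                   seed = 202L)
  })
}

# annotated-proteome views of the two tiny species (truth-based)
truth_proteome <- function(cluster) {
  list(ann = cluster$truth,
       proteins = vapply(cluster$templates[cluster$truth$genes$gene],
                         `[[`, "", "protein"))
}

# random protein / DNA with a local seed
rand_protein <- function(n, seed) {
  withr::with_seed(seed, edcscan:::.random_protein(n))
}
rand_dna <- function(n, seed) {
  withr::with_seed(seed, edcscan:::.random_dna(n))
}
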