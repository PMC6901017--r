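# shared simulated screen, built once per test session: a medium-sized
# three-strain screen with duplicated genes, plus scored matrices, calls
# and the reference batch-pair null
screen_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    st <- simulate_screen(n_genes = 600, n_conditions = 10,
                          n_duplicates = 40, grid_shape = c(16L, 48L),
                          seed = 101)
    sm_r1 <- score_simulated_strain(st, "ref", batch = 1)
    sm_r2 <- score_simulated_strain(st, "ref", batch = 2, seed_offset = 5000)
    sm_a <- score_simulated_strain(st, "strainA")
    sm_b <- score_simulated_strain(st, "strainB")
    cache <<- list(
      st = st, sm_r1 = sm_r1, sm_r2 = sm_r2, sm_a = sm_a, sm_b = sm_b,
      calls_a = call_phenotypes(sm_a), calls_b = call_phenotypes(sm_b),
      null = build_null(sm_r1, sm_r2))
    cache
  }
})

pair_key <- function(df) paste(df$gene, df$condition)

# small raw plate with a deterministic size surface and optional layout
toy_plate <- function(sizes, stage = "raw", layout = NULL, ...) {
  plate_grid(sizes, plate_id = "toy", strain = "s", condition = "c",
             stage = stage, layout = layout, ...)
}

# direct score_matrix builder for ops that do not need the plate pipeline
toy_scores <- function(S, strain = "s", n_rep = NULL, normalized = TRUE) {
  if (is.null(n_rep)) n_rep <- matrix(4L, nrow(S), ncol(S), dimnames = dimnames(S))
  score_matrix(S, n_rep, strain = strain, normalized = normalized)
}
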