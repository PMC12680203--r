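# shared test helpers: small state builders and randomized corpora

state_from <- function(values, order = 2L, l_max = max(order, 4L)) {
  x <- as.matrix(values)
  st <- moment_state(ncol(x), order = order, l_max = l_max)
  for (i in seq_len(nrow(x))) st <- absorb_point(st, x[i, ])
  st
}

# seeded corpus of random point sequences in [0,1]^d
random_sequences <- function(n_seq, seed, max_len = 50, max_d = 5) {
  set.seed(seed)
  lapply(seq_len(n_seq), function(i) {
    d <- sample.int(max_d, 1)
    len <- sample(2:max_len, 1)
    matrix(runif(len * d), nrow = len, ncol = d)
  })
}

# seeded random classification instances: class point sets + a query point
random_instances <- function(n_inst, seed, max_classes = 3, max_d = 4,
                             max_pts = 30) {
  set.seed(seed)
  lapply(seq_len(n_inst), function(i) {
    m <- sample(2:max_classes, 1)
    d <- sample.int(max_d, 1)
    sets <- lapply(seq_len(m), function(j) {
      matrix(runif(sample(2:max_pts, 1) * d), ncol = d)
    })
    names(sets) <- paste0("c", seq_len(m))
    list(sets = sets, x = runif(d), order = sample(1:4, 1))
  })
}

instance_to_df <- function(inst) {
  dplyr::bind_rows(lapply(names(inst$sets), function(nm) {
    m <- inst$sets[[nm]]
    colnames(m) <- paste0("x", seq_len(ncol(m)))
    dplyr::mutate(tibble::as_tibble(m), class = nm)
  }))
}

two_gaussians <- function(n = 100, sep = 6, sd = 0.05, seed = 1) {
  spec <- generator_spec(n = c(a = n, b = n),
                         location = c(0.5 - sep * sd / 2, 0.5 + sep * sd / 2),
                         scale = sd)
  synth_tabular(spec, seed = seed)
}
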