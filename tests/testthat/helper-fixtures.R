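# Shared generators for property-style tests. Everything is built in code;
# no binary fixtures.

# Random small instance with overdispersed counts; every species is
# guaranteed some abundance so targets are reachable.
random_instance <- function(seed, n_pu = 12, n_sp = 6, p = 0.5, spf = 100) {
  set.seed(seed)
  a <- matrix(rnbinom(n_sp * n_pu, size = 1, mu = 30), n_sp, n_pu,
              dimnames = list(sprintf("s%d", seq_len(n_sp)),
                              sprintf("p%02d", seq_len(n_pu))))
  for (s in seq_len(n_sp))
    if (sum(a[s, ]) == 0) a[s, sample.int(n_pu, 1)] <- 5L
  problem_instance(a, target_fraction = p, spf = spf)
}

fixture_instance <- function(p, spf = 100) {
  fx <- make_fixture()
  problem_instance(fx$counts, fx$pu, target_fraction = p, spf = spf)
}

# Cheap annealing schedule for tests on small instances.
test_config <- function(...) {
  args <- utils::modifyList(list(iterations = 2000, n_solutions = 20,
                                 seed = 1), list(...))
  do.call(run_config, args)
}
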