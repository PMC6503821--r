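# Shared expensive fixtures, built once per test run on first use.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# separable two-model fixture at classifier-power scale
separable_big <- function()
  cached("separable_big", make_separable_fixture(n_per_model = 10000L,
                                                 n_loci = 150L, seed = 101L))

# small separable fixture for unit tests
separable_small <- function()
  cached("separable_small", make_separable_fixture(n_per_model = 600L,
                                                   n_loci = 150L, seed = 102L))

# reconstructed inland scenario reference table at cross-validation scale
inland_table_big <- function()
  cached("inland_table_big",
         build_reference_table(inland_migration_model(), 10000L, 500L,
                               seed = 202L))
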