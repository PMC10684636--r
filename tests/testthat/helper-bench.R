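# Heavy shared fixtures for the end-to-end scientific checks; computed once
# per test run and reused across tests.

bench_scenario <- function() {
  memo("bench_scenario", function() scenario_benchmark(seeds = 1:5))
}

bench_halo <- function() {
  memo("bench_halo", function() halo_benchmark(seed = 7L))
}
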