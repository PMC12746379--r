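# Shared fixture builders (all generated in code, no stored data).

water_only_system <- function(T1 = 1.7, T2 = 0.07) {
  pool_system(water = pool(0, 1, 0, T1, T2))
}

# simple amide + MT system used across tests
amide_system <- function(f_amide = 0.002, k_amide = 50) {
  pool_system(
    water = pool(0, 1, 0, 1.7, 0.07),
    solutes = list(pool(3.5, f_amide, k_amide, 1.5, 0.002)),
    mt = pool(-2.5, 0.07, 30, 1.3, 1e-5)
  )
}

# random 4-pool (water + 2 solutes + MT) system with moderate parameters
random_four_pool <- function() {
  pool_system(
    water = pool(0, 1, 0, runif(1, 1.2, 2.2), runif(1, 0.05, 0.1)),
    solutes = list(
      pool(runif(1, 2, 4), runif(1, 1e-3, 4e-3), runif(1, 30, 300), 1.5,
           runif(1, 2e-3, 1e-2)),
      pool(runif(1, -4, -1), runif(1, 1e-3, 4e-3), runif(1, 10, 100), 1.3,
           runif(1, 2e-3, 1e-2))
    ),
    mt = pool(-2.5, runif(1, 0.03, 0.1), runif(1, 20, 50), 1.3, 1e-5)
  )
}

small_schedule <- function(n = 25) {
  offset_schedule(seq(-5, 5, length.out = n))
}
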