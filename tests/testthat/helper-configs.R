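# Shared small configurations so unit tests stay fast; acceptance tests
# build their own, larger grids.
cfg_small <- function(n = 128) optical_config(grid_n = n)
cfg_mid <- function() optical_config(grid_n = 256)

hw_mask <- function(cfg) annular_mask(config = cfg)

zero_wavefront <- function(cfg) matrix(0, cfg$grid_n, cfg$grid_n)
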