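#' Pipeline configuration
#'
#' Central registry of every numeric constant used by the extraction and
#' modelling pipeline. `pvq_config()` returns the defaults, optionally
#' overridden by named arguments; unknown keys are rejected so typos fail
#' loudly. The defaults reproduce the pipeline's canonical constants:
#' 256-sample frames with 100-sample overlap for the filterbank cepstra,
#' 128 ERB-spaced Gammatone channels, an 18th-order LP model on 20 ms
#' non-overlapping frames, a 23-channel auditory filterbank with 4-128 Hz
#' modulation bands for SRMR, a 0.95 PCA variance threshold, and a 0.2 test
#' fraction.
#'
#' @param ... Named overrides of default keys.
#' @return A named list of class `pvq_config`.
#' @export
#' @examples
#' cfg <- pvq_config(rpde_t_max = 800)
#' cfg$gfcc_frame_len
pvq_config <- function(...) {
  defaults <- list(
    # audio_io
    target_rate      = 16000,
    segment_s        = 2.0,
    # GFCC (filterbank cepstra)
    gfcc_frame_len   = 256L,
    gfcc_overlap     = 100L,    # hop = frame_len - overlap = 156
    gfcc_window      = "hamming",
    gfcc_n_filters   = 128L,
    gfcc_fmin        = 50,
    gfcc_fmax        = 8000,
    gfcc_n_coef      = 30L,     # DCT coefficients kept (excluding c0)
    gfcc_include_c0  = FALSE,
    # LCQA (linear-prediction quality descriptors)
    lcqa_frame_ms    = 20,
    lcqa_lp_order    = 18L,
    lcqa_n_spectrum  = 512L,
    # SRMR
    srmr_n_channels  = 23L,
    srmr_cf_min      = 125,
    srmr_mod_lo      = 4,
    srmr_mod_hi      = 128,
    srmr_n_mod       = 8L,
    srmr_env_rate    = 256,
    # ModA
    moda_band_edges  = c(300, 600, 1200, 2400, 4800),
    moda_env_rate    = 20,
    moda_mod_lo      = 0.5,
    moda_mod_hi      = 8,
    # traditional measures
    f0_min           = 60,
    f0_max           = 400,
    hnr_frame_s      = 0.04,
    hnr_hop_s        = 0.01,
    hnr_clamp        = c(-10, 40),
    cpps_frame_len   = 1024L,
    cpps_hop_s       = 0.002,
    cpps_time_smooth = 10L,
    cpps_quef_smooth = 10L,
    # RPDE
    rpde_embed_dim   = 4L,
    rpde_delay       = 35L,
    rpde_radius      = 0.12,    # x signal SD
    rpde_t_max       = 1000L,
    rpde_stride      = 2L,      # reference-point subsampling beyond 2 s
    # modelling
    test_frac        = 0.2,
    pca_threshold    = 0.95,
    mc_n_iter        = 2000L,
    mc_val_frac      = 0.25,
    svr_cost         = 10,
    svr_epsilon      = 1,       # VAS units
    n_repeats        = 20L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == ""))
      stop(sprintf("unknown config key(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    defaults[names(overrides)] <- overrides
  }
  structure(defaults, class = "pvq_config")
}

#' @export
print.pvq_config <- function(x, ...) {
  cat("<pvq_config>\n")
  for (k in names(x))
    cat(sprintf("  %-16s %s\n", k, paste(format(x[[k]]), collapse = " ")))
  invisible(x)
}
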