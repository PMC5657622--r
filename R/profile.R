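#' Sensitivity profiles for overlap detection
#'
#' Overlap acceptance is controlled by a small set of constants. The base
#' values below were chosen for this implementation and validated by its
#' property tests; they are ordinary configuration, not measured quantities:
#'
#' * `c0` — pseudocount in the ratio `R = (B + c0) / (B + G)`.
#' * `c1` — maximum accepted best ratio `R1`.
#' * `c2` — separation factor: reject as ambiguous when `R1 * c2 > R2`.
#' * `c3` — floor on the second-best ratio `R2` (a very good runner-up also
#'   means ambiguity).
#' * `c4` — minimum matches in the overlap (bases).
#' * `c5` — expected-mismatch multiplier: reject when `B > E * c5`.
#' * `c6_insert` — minimum insert size (bases).
#' * `c6_prob` — floor on the binomial tail probability of the observed
#'   match/mismatch pattern.
#'
#' Presets form a monotone ladder from `ustrict` to `xloose`: each step
#' looser doubles `c1` and divides `c2` by 1.4, so any pair merged at a
#' stricter preset is also merged at every looser one. `xstrict`/`ustrict`
#' additionally require flat mode (minimum-mismatch offset selection) to
#' agree with ratio mode; `xloose` uses a flat-mode result when ratio mode
#' produced none.
#'
#' @param preset One of `"ustrict"`, `"xstrict"`, `"vstrict"`, `"strict"`,
#'   `"default"`, `"loose"`, `"vloose"`, `"xloose"`.
#' @param ... Named overrides of individual fields (e.g. `c4 = 15`,
#'   `ouq = TRUE`).
#' @return An object of class `sensitivity_profile` (a named list).
#' @examples
#' sensitivity_profile("strict")
#' sensitivity_profile("default", ouq = TRUE)
#' @export
sensitivity_profile <- function(preset = "default", ...) {
  ladder <- c(ustrict = 4L, xstrict = 3L, vstrict = 2L, strict = 1L,
              default = 0L, loose = -1L, vloose = -2L, xloose = -3L)
  preset <- match.arg(preset, names(ladder))
  lvl <- ladder[[preset]]
  p <- list(
    c0 = 0.4,
    c1 = min(0.12 * 2^(-lvl), 0.96),
    c2 = max(6 * 1.4^lvl, 1),
    c3 = 0.05,
    c4 = 12L,
    c5 = 8,
    c6_insert = 35L,
    c6_prob = 1e-5,
    use_flat_confirm = preset %in% c("xstrict", "ustrict"),
    use_flat_rescue = preset == "xloose",
    ouq = FALSE,
    qcap = 41L,
    v_max = 30,
    h_thresh = 3.2,
    adapter_mismatch_frac = 0.25,
    preset_name = preset
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown profile field(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$c0 > 0, p$c1 > 0, p$c1 < 1, p$c2 >= 1, p$c4 >= 1,
            p$c6_insert >= 1)
  p$c4 <- as.integer(p$c4)
  p$c6_insert <- as.integer(p$c6_insert)
  p$qcap <- as.integer(p$qcap)
  structure(p, class = "sensitivity_profile")
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat(sprintf("<sensitivity_profile> preset '%s'\n", x$preset_name))
  cat(sprintf("  ratio: c0=%.3g c1=%.4g c2=%.3g c3=%.3g\n",
              x$c0, x$c1, x$c2, x$c3))
  cat(sprintf("  gates: c4=%d c5=%.3g c6_insert=%d c6_prob=%.1e\n",
              x$c4, x$c5, x$c6_insert, x$c6_prob))
  cat(sprintf("  flags: flat_confirm=%s flat_rescue=%s ouq=%s\n",
              x$use_flat_confirm, x$use_flat_rescue, x$ouq))
  invisible(x)
}

#' Preset names, strictest first
#'
#' @return Character vector of the eight preset names in ladder order.
#' @export
preset_ladder <- function() {
  c("ustrict", "xstrict", "vstrict", "strict", "default", "loose",
    "vloose", "xloose")
}
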