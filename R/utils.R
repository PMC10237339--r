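#' @importFrom stats rpois runif rnorm rlnorm qnorm pnorm mad median sd
#'   setNames aov anova lm coef var t.test wilcox.test ansari.test var.test
#'   p.adjust quantile IQR approx uniroot runmed complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nmj <- function(...) stop(sprintf(...), call. = FALSE)

# odd window length >= 3 for running-median filters
odd_window <- function(n) {
  n <- max(3L, as.integer(round(n)))
  if (n %% 2L == 0L) n + 1L else n
}

# deterministic 32-bit seed from a master seed plus a stage/group/replicate label,
# so that stages and replicates draw from uncorrelated streams
derive_seed <- function(master_seed, stage, group = "", replicate = 0L) {
  h <- 0
  for (ch in utf8ToInt(paste0(stage, "/", group))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(master_seed) * 48271 + h * 16807 + replicate * 69621) %% 2147483629 + 1)
}

# truncated-normal draws by inverse-CDF (keeps intensity components on bounded
# supports without clipping spikes in the histogram)
rtnorm <- function(n, mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(runif(n, pl, pu), mean, sd)
}
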