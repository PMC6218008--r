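# Critical values (degrees) of Rao's spacing statistic U under the uniform
# null, at significance levels 0.10 / 0.05 / 0.01. Tabulated by seeded
# Monte Carlo (1e6 replicates per sample size up to n = 50, >= 3e5 above);
# values agree with the classical published tables to within ~0.1 degree
# at the sample sizes those tables report. Lookups interpolate linearly in
# n between rows; n beyond the last row uses the last row (conservative,
# since critical values decrease in n).
.rao_crit <- local({
  tab <- matrix(c(
      4, 168.05, 186.51, 221.30,
      5, 168.78, 183.49, 212.02,
      6, 166.19, 180.45, 206.55,
      7, 164.91, 177.76, 202.46,
      8, 163.56, 175.75, 198.54,
      9, 162.38, 173.69, 195.11,
     10, 161.29, 172.09, 192.52,
     11, 160.29, 170.41, 189.81,
     12, 159.36, 169.11, 187.62,
     13, 158.48, 167.83, 185.77,
     14, 157.77, 166.79, 183.69,
     15, 157.04, 165.67, 182.12,
     16, 156.49, 164.83, 180.76,
     17, 155.81, 163.98, 179.37,
     18, 155.28, 163.19, 178.25,
     19, 154.85, 162.48, 177.22,
     20, 154.28, 161.76, 176.05,
     21, 153.83, 161.16, 174.98,
     22, 153.45, 160.59, 174.08,
     23, 153.05, 160.00, 173.24,
     24, 152.65, 159.46, 172.40,
     25, 152.30, 159.00, 171.70,
     26, 152.00, 158.52, 170.95,
     27, 151.62, 158.06, 170.17,
     28, 151.38, 157.67, 169.63,
     29, 151.05, 157.21, 168.86,
     30, 150.81, 156.85, 168.44,
     35, 149.61, 155.15, 165.90,
     40, 148.60, 153.81, 163.69,
     45, 147.74, 152.64, 161.96,
     50, 147.06, 151.71, 160.44,
     75, 144.55, 148.35, 155.42,
    100, 143.03, 146.27, 152.46,
    150, 141.15, 143.81, 148.87,
    200, 140.05, 142.35, 146.68,
    300, 138.70, 140.55, 144.10,
    500, 137.35, 138.79, 141.46,
    750, 136.45, 137.62, 139.79,
   1000, 135.93, 136.95, 138.86
  ), ncol = 4, byrow = TRUE,
  dimnames = list(NULL, c("n", "0.10", "0.05", "0.01")))
  tab
})

# Critical value of Rao's U for sample size n at a tabulated alpha,
# linearly interpolated in n.
rao_critical_value <- function(n, alpha) {
  col <- match(sprintf("%.2f", alpha), colnames(.rao_crit))
  if (is.na(col)) {
    stop("configuration error: alpha must be one of 0.10, 0.05, 0.01",
         call. = FALSE)
  }
  ns <- .rao_crit[, "n"]
  if (n <= ns[1]) return(.rao_crit[1, col])
  if (n >= ns[length(ns)]) return(.rao_crit[length(ns), col])
  stats::approx(ns, .rao_crit[, col], xout = n)$y
}
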