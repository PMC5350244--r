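#' Published F-test p-values for dopamine de-synchronisation of PY neurons
#'
#' The 44 variance-ratio F-test p-values reported for the dopamine
#' experiment on pyloric constrictor (PY) neurons of the crab
#' stomatogastric ganglion: 11 neuron pairs (rows, from four preparations)
#' by four salient-point kinds (columns), each comparing the standard
#' deviation of matched temporal delays before and after dopamine exposure.
#' 22 of the 44 values fall below the 0.05 significance level, all but one
#' of the reported significant changes being variance increases — the
#' de-synchronisation signature.
#'
#' @param long if `TRUE`, return a long-format data frame with columns
#'   `pair`, `kind`, `p_value` (one row per comparison, suitable for
#'   [count_significant()]); otherwise the 11 x 4 wide table.
#' @return a data frame of p-values.
#' @examples
#' count_significant(py_delay_pvalues(long = TRUE), alpha = 0.05)$n_significant
#' @export
py_delay_pvalues <- function(long = FALSE) {
  path <- system.file("extdata", "py_delay_ftest_pvalues.csv",
                      package = "vsdtrace", mustWork = TRUE)
  wide <- utils::read.csv(path)
  if (!long) return(wide)
  kinds <- c("max_slope", "min_slope", "plateau_begin", "plateau_end")
  long_df <- do.call(rbind, lapply(kinds, function(k)
    data.frame(pair = wide$pair, kind = k, p_value = wide[[k]],
               stringsAsFactors = FALSE)))
  long_df[order(long_df$pair, match(long_df$kind, kinds)), ]
}
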