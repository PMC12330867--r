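#' Published cohort calibration table
#'
#' Group means and standard deviations of the young-adult (YA) and old-adult
#' (OA) marmoset study population that the synthetic-cohort generator is
#' calibrated to: biology (heart rate, weight, tissue volumes), per-vessel
#' and total per-cycle blood volumes, perfusion and CBF. The per-vessel rows
#' are the generator's sampling targets; the total rows are the published
#' totals (used e.g. to check additivity of the table).
#'
#' @return data.frame with columns `group` ("YA"/"OA"), `metric`, `mean`,
#'   `sd`, `n`, `units`
#' @export
calibration_targets <- function() {
  row <- function(group, metric, mean, sd, n, units)
    data.frame(group = group, metric = metric, mean = mean, sd = sd, n = n,
               units = units)
  rbind(
    row("YA", "heart_rate", 189, 58, 9, "bpm"),
    row("OA", "heart_rate", 152, 42, 8, "bpm"),
    row("YA", "weight", 373, 41, 10, "g"),
    row("OA", "weight", 391, 38, 9, "g"),
    row("YA", "gm_volume", 4084, 628, 10, "ul"),
    row("OA", "gm_volume", 4256, 466, 9, "ul"),
    row("YA", "wm_volume", 2669, 260, 10, "ul"),
    row("OA", "wm_volume", 2831, 292, 9, "ul"),
    row("YA", "csf_volume", 941, 335, 10, "ul"),
    row("OA", "csf_volume", 1119, 337, 9, "ul"),
    row("YA", "volume_BT", 19.0, 4.3, 7, "ul/cc"),
    row("OA", "volume_BT", 30.3, 6.7, 7, "ul/cc"),
    row("YA", "volume_RC", 13.2, 5.1, 7, "ul/cc"),
    row("OA", "volume_RC", 19.3, 6.7, 7, "ul/cc"),
    row("YA", "volume_LC", 15.5, 4.5, 7, "ul/cc"),
    row("OA", "volume_LC", 19.5, 9.0, 7, "ul/cc"),
    row("YA", "volume_carotids", 28.7, 7.8, 7, "ul/cc"),
    row("OA", "volume_carotids", 38.8, 14.6, 7, "ul/cc"),
    row("YA", "volume_arteries", 47.7, 10.9, 7, "ul/cc"),
    row("OA", "volume_arteries", 69.2, 18.4, 7, "ul/cc"),
    row("YA", "volume_SS", 6.2, 3.7, 7, "ul/cc"),
    row("OA", "volume_SS", 5.6, 2.4, 7, "ul/cc"),
    row("YA", "volume_StS", 6.8, 1.8, 7, "ul/cc"),
    row("OA", "volume_StS", 5.7, 3.2, 7, "ul/cc"),
    row("YA", "volume_sinuses", 13.0, 3.4, 7, "ul/cc"),
    row("OA", "volume_sinuses", 11.3, 5.0, 7, "ul/cc"),
    row("YA", "perfusion", 9.0, 2.3, 7, "ml/min"),
    row("OA", "perfusion", 11.0, 4.3, 7, "ml/min"),
    row("YA", "cbf", 126.4, 20.8, 7, "ml/min/100g"),
    row("OA", "cbf", 148.8, 58.6, 7, "ml/min/100g")
  )
}
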