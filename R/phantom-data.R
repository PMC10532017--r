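# Empirical tumor slice-count distribution of the 922-patient DukeBC cohort:
# number of patients (count) per tumor slice count (n_slices), support 2..131.
# Used as the default sampling distribution of the phantom generator.
duke_slice_count_table <- function() {
  data.frame(
    n_slices = c(2:60, 62:77, 79:82, 85, 89, 90, 95, 96, 97, 102, 108, 111, 119, 131),
    count = c(
      # 2..16
      1, 4, 8, 3, 10, 15, 19, 27, 24, 38, 43, 44, 35, 36, 33,
      # 17..31
      34, 39, 26, 26, 30, 32, 19, 23, 24, 21, 23, 18, 14, 8, 17,
      # 32..46
      17, 12, 11, 12, 4, 9, 10, 7, 4, 4, 7, 8, 6, 4, 10,
      # 47..60
      6, 3, 6, 4, 7, 4, 4, 4, 3, 4, 3, 1, 2, 1,
      # 62..77
      2, 3, 3, 3, 3, 1, 1, 5, 1, 1, 1, 1, 2, 1, 1, 1,
      # 79..82, 85, 89, 90, 95, 96, 97, 102, 108, 111, 119, 131
      1, 1, 3, 4, 1, 1, 1, 1, 1, 1, 1, 2, 1, 1, 1))
}
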