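# shared fixture builders: tiny colony tables and schedules built in code

make_colonies <- function(n = 1, g = 12.5, p_net = 6.4, respiration = 5.0,
                          sa = 0.0013) {
  tibble::tibble(
    colony_id = sprintf("c%02d", seq_len(n)),
    chamber_id = sprintf("F%02d", seq_len(n)),
    surface_area_m2 = rep_len(sa, n),
    g = rep_len(g, n), p_net = rep_len(p_net, n),
    respiration = rep_len(respiration, n))
}

make_schedule <- function(n_light = 1, n_dark = 1, dur = 3) {
  light <- tibble::tibble(
    cycle = sprintf("L%d", seq_len(n_light)), phase = "light",
    start_h = (seq_len(n_light) - 1) * (dur + 0.5))
  dark <- tibble::tibble(
    cycle = sprintf("D%d", seq_len(n_dark)), phase = "dark",
    start_h = max(light$start_h) + dur + 1.5 +
      (seq_len(n_dark) - 1) * (dur + 0.5))
  out <- dplyr::bind_rows(light, dark)
  out$end_h <- out$start_h + dur
  out
}

# noise-free simulate -> reduce; returns the colonies rate table
reduce_noiseless <- function(colonies, schedule = make_schedule(),
                             volume_l = 1.05, ...) {
  s <- simulate_incubation(colonies, schedule, volume_l = volume_l,
                           noise_ta = 0, noise_o2 = 0, ...)
  process_incubation_set(s, colonies, attr(s, "volumes"))
}
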