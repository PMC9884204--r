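# Small, fast profiles used across the tests. Durations are kept short
# (a few hundred seconds) so the whole suite stays well inside budget.

vcv_profile <- function(C0 = 50, R_aw = 0, k = 0, sigma = 0,
                        VT = 500, RR = 12, IE = 0.667, PEEP = 5,
                        iap_target = 14, t_ins = 60, t_def = 250,
                        seed = 1L, ...) {
  subject_profile(
    "test_vcv",
    lung = lung_model_params(C0 = C0, R_aw = R_aw, k = k, C_min = 10),
    iap = iap_profile_params(iap_target, t_ins, t_def, ramp_tau = 15,
                             sigma = sigma),
    settings_schedule = list(list(
      time = 0,
      settings = ventilation_settings("VCV", VT_target = VT, RR = RR,
                                      IE = IE, PEEP_set = PEEP))),
    seed = seed, ...)
}

pcv_profile <- function(C0 = 40, R_aw = 0.01, k = 0, sigma = 0,
                        Pins = 20, RR = 12, IE = 0.667, PEEP = 5,
                        iap_target = 12, t_ins = 60, t_def = 250,
                        seed = 1L, ...) {
  subject_profile(
    "test_pcv",
    lung = lung_model_params(C0 = C0, R_aw = R_aw, k = k, C_min = 10),
    iap = iap_profile_params(iap_target, t_ins, t_def, ramp_tau = 15,
                             sigma = sigma),
    settings_schedule = list(list(
      time = 0,
      settings = ventilation_settings("PCV", Pins_max = Pins, RR = RR,
                                      IE = IE, PEEP_set = PEEP))),
    seed = seed, ...)
}

# closed-form tidal volume of the constant-compliance PCV breath
pcv_vt_closed_form <- function(dP, C, R, T_insp) {
  dP * C * (1 - exp(-T_insp / (R * C)))
}
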