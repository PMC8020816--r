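# Shared synthetic fixtures, built in code.

# 5-h OGTT sampling schedule and a canonical rise-then-decay C-peptide curve
t5_times <- c(0, 10, 20, 30, 60, 90, 120, 150, 180, 240, 300)
t5_cp <- c(0.5, 0.8, 1.3, 1.8, 2.4, 2.6, 2.5, 2.2, 1.9, 1.3, 0.8)

t2_times <- c(0, 30, 60, 90, 120)
t2_cp <- c(0.5, 1.6, 2.2, 2.3, 2.1)

# A smooth full-cycle sensitivity profile spanning [-2, 3]
smooth_s_profile <- function(phase = 0, n = 11) {
  0.5 + 2.5 * sin(2 * pi * (seq_len(n) - 1) / (n - 1) + phase)
}

# Ground-truth subject on the 5-h schedule
make_truth_subject <- function(s_gluca, k_gluca = 0.005, k_dcprem = 0.155,
                               gluca_b = 70, noise_cv = 0, seed = 1,
                               times = t5_times, cp = t5_cp) {
  truth <- model_params(k_gluca, k_dcprem, s_gluca)
  syn <- synthesize_from_truth(truth, times, cp, gluca_b = gluca_b,
                               noise_cv = noise_cv, seed = seed)
  c(syn, list(truth = truth))
}

# A series whose suprabasal C-peptide input is (up to a 1e-6-min ramp) the
# constant A from t = 0 on: the OgttSeries contract pins the input to 0 at
# t = 0, so a jump sample just after 0 emulates the constant input.
constant_input_series <- function(A, t_end = 30, gluca_b = 60, cp_b = 0.5) {
  ogtt_series(c(0, 1e-6, t_end / 2, t_end),
              rep(gluca_b, 4),
              c(cp_b, cp_b + A, cp_b + A, cp_b + A))
}

# Minimal fit-shaped object for functions that only need params/residuals
fake_fit <- function(params = NULL, residuals = NULL, step = 1,
                     weights = reg_weights(0.1, 1)) {
  structure(list(params = params, residuals = residuals, step = step,
                 weights = weights, times = NULL),
            class = "gluca_fit")
}

# Hand-made per-subject indices for the population statistics
make_indices <- function(mean_full, mean_3h = mean_full, mean_2h = mean_full,
                         auc_dcp = 1, auc_gluca = 1) {
  structure(list(mean_sgluca_full = mean_full, mean_sgluca_3h = mean_3h,
                 mean_sgluca_2h = mean_2h, auc_dcp_remote = auc_dcp,
                 auc_gluca_below_basal = auc_gluca),
            class = "gluca_indices")
}

# Check one generated subject against its template (truncation + sign rules)
subject_obeys_template <- function(s, tpl) {
  in_band <- function(y, m, sd) {
    all(y >= pmax(0, m - 1.96 * sd) - 1e-12 & y <= m + 1.96 * sd + 1e-12)
  }
  signs_ok <- function(y, m) {
    ds <- sign(diff(m))
    dy <- sign(diff(y))
    all(ds == 0 | dy == 0 | dy == ds)
  }
  in_band(s$glucagon, tpl$gluca_mean, tpl$gluca_sd) &&
    in_band(s$cpeptide, tpl$cp_mean, tpl$cp_sd) &&
    signs_ok(s$glucagon, tpl$gluca_mean) &&
    signs_ok(s$cpeptide, tpl$cp_mean)
}
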