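# Fixtures built in code: a two-cow trial with hand-computable arithmetic,
# and small simulator configs.

# C1 (diet D1): 7740 g DM consumed over 5 d, no orts, ADL 43 g/kg in hay,
#   93 g/kg in feces, 3760 g fecal DM.
# C2 (diet D2): 10000 g offered, 1000 g orts (ADL 50 g/kg), hay ADL 45,
#   feces ADL 90, 4000 g fecal DM.
hand_trial <- function() {
  design <- tibble::tibble(
    animal_id = c("C1", "C2"), block = "B1",
    period_id = "P1", diet_id = c("D1", "D2")
  )
  diets <- tibble::tibble(
    diet_id = c("D1", "D2"), cp = c(79, 111), ndf = c(768, 712),
    adf = c(428, 348), total_ash = c(61, 87), dm = c(885, 872),
    ADL = c(43, 45)
  )
  intake <- dplyr::bind_rows(
    tibble::tibble(animal_id = "C1", period_id = "P1", day = 1:5,
                   offered_mass_g_dm = 1548, ort_mass_g_dm = 0),
    tibble::tibble(animal_id = "C2", period_id = "P1", day = 1:5,
                   offered_mass_g_dm = 2000, ort_mass_g_dm = 200)
  )
  fecal <- dplyr::bind_rows(
    tibble::tibble(animal_id = "C1", period_id = "P1", day = 1:5, fecal_dm_g = 752),
    tibble::tibble(animal_id = "C2", period_id = "P1", day = 1:5, fecal_dm_g = 800)
  )
  assays <- tibble::tibble(
    material_id = rep(c("hay:C1:P1", "hay:C2:P1", "ort:C2:P1",
                        "feces:C1:P1", "feces:C2:P1"), each = 2),
    marker_name = "ADL",
    rep_index = rep(1:2, 5),
    value_g_per_kg_dm = rep(c(43, 45, 50, 93, 90), each = 2)
  )
  marker_trial(design, diets, intake, fecal, assays)
}

# Noise-free config with a single configured recovery for every marker.
noise_free_config <- function(recovery = 1, seed = 1) {
  sim_config(
    seed = seed, assay_cv = 0,
    marker_params = dplyr::mutate(default_marker_params(),
                                  true_recovery = recovery)
  )
}
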