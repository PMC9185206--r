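# shared fixtures: biometry records, cohort CSV text, and the independent
# paraxial thick-lens oracle used to cross-check the ray tracer

make_record <- function(al = 23.5, k = 43, acd = 3.2, lt = 4.5, cct = 540,
                        k1 = k, k2 = k) {
  data.frame(patient_id = "P1", eye = "OD", al = al, acd = acd, lt = lt,
             cct = cct, k1 = k1, k2 = k2, wtw = 11.8, pupil = 3.0,
             iol_model = NA_character_, iol_power = NA_real_,
             postop_se = NA_real_, stringsAsFactors = FALSE)
}

cohort_csv_header <- paste(
  "patient_id,eye,al_mm,acd_mm,lt_mm,cct_um,k1_d,k2_d,wtw_mm,pupil_mm",
  "iol_model,iol_power_d,postop_se_d", sep = ",")

write_cohort_text <- function(rows, path = withr::local_tempfile(fileext = ".csv",
                                                                 .local_envir = parent.frame())) {
  writeLines(c(cohort_csv_header, rows), path)
  path
}

# Paraxial (Gaussian, thick-lens) refraction of a built eye meridian:
# back-propagates the vergence required at the retina through all four
# surfaces and converts to the spectacle plane. Entirely independent of the
# exact ray tracer (no intersections, no Snell).
paraxial_refraction <- function(eye, meridian = 1, vertex_mm = 12) {
  s <- eye$meridians[[meridian]]
  v <- 1000 * s[[4]]$n_after / (eye$retina_z - s[[4]]$z_vertex)
  for (i in 4:1) {
    p_i <- (s[[i]]$n_after - s[[i]]$n_before) * 1000 / s[[i]]$radius
    v <- v - p_i
    if (i > 1) {
      d <- (s[[i]]$z_vertex - s[[i - 1]]$z_vertex) / 1000
      v <- v / (1 + d * v / s[[i]]$n_before)
    }
  }
  v / (1 + vertex_mm / 1000 * v)
}

paraxial_se <- function(eye, vertex_mm = 12) {
  mean(c(paraxial_refraction(eye, 1, vertex_mm),
         paraxial_refraction(eye, 2, vertex_mm)))
}
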