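# Printed reference tables used by the acceptance tests.

# 12 (K, Vm) scenarios and 15 indices; printed to the precision shown.
printed_table3 <- function() {
  scen <- expand.grid(Vm = c(0.05, 0.1, 0.2), K = c(0.005, 0.01, 0.05, 0.1))
  vals <- list(
    auc_exact = c(0.678, 0.746, 0.832, 0.666, 0.730, 0.814,
                  0.635, 0.690, 0.765, 0.622, 0.672, 0.742),
    auc_binormal_eq = c(0.677, 0.742, 0.821, 0.665, 0.726, 0.803,
                        0.634, 0.686, 0.754, 0.621, 0.669, 0.731),
    auc_binormal = c(0.679, 0.747, 0.833, 0.667, 0.731, 0.815,
                     0.636, 0.691, 0.766, 0.623, 0.673, 0.744),
    pce_0.1 = c(0.258, 0.350, 0.505, 0.241, 0.323, 0.460,
                0.201, 0.255, 0.346, 0.182, 0.224, 0.293),
    pce_0.2 = c(0.421, 0.530, 0.691, 0.401, 0.500, 0.650,
                0.349, 0.421, 0.535, 0.323, 0.382, 0.474),
    pce_0.5 = c(0.746, 0.831, 0.924, 0.729, 0.812, 0.906,
                0.681, 0.752, 0.845, 0.656, 0.719, 0.805),
    var_risk = c(1.23e-05, 2.90e-05, 7.97e-05, 4.06e-05, 9.27e-05, 2.39e-04,
                 5.68e-04, 1.21e-03, 2.75e-03, 1.60e-03, 3.34e-03, 7.20e-03),
    var_ratio = c(0.0025, 0.0058, 0.0160, 0.0041, 0.0094, 0.0241,
                  0.0120, 0.0255, 0.0578, 0.0178, 0.0371, 0.0800),
    mean_risk_cases = c(0.0075, 0.0108, 0.0209, 0.0141, 0.0193, 0.0339,
                        0.0614, 0.0743, 0.1049, 0.1160, 0.1334, 0.1720),
    mean_risk_noncases = c(0.0050, 0.0050, 0.0049, 0.0100, 0.0099, 0.0098,
                           0.0494, 0.0487, 0.0472, 0.0982, 0.0963, 0.0921),
    slope = c(0.0025, 0.0058, 0.0160, 0.0041, 0.0094, 0.0241,
              0.0120, 0.0255, 0.0577, 0.0178, 0.0371, 0.0799),
    risk_p10 = c(0.0017, 0.0008, 0.0002, 0.0037, 0.0020, 0.0006,
                 0.0238, 0.0153, 0.0066, 0.0538, 0.0377, 0.0191),
    risk_p90 = c(0.0094, 0.0111, 0.0126, 0.0182, 0.0214, 0.0250,
                 0.0817, 0.0957, 0.1154, 0.1537, 0.1778, 0.2142),
    rr = c(5.68, 13.21, 58.42, 4.95, 10.76, 42.06,
           3.44, 6.23, 17.56, 2.85, 4.72, 11.24),
    range = c(0.0078, 0.0102, 0.0124, 0.0145, 0.0194, 0.0244,
              0.0580, 0.0803, 0.1088, 0.0998, 0.1401, 0.1951)
  )
  list(scen = scen, vals = vals,
       # decimals printed per index (NA = 3 significant figures)
       decimals = c(auc_exact = 3, auc_binormal_eq = 3, auc_binormal = 3,
                    pce_0.1 = 3, pce_0.2 = 3, pce_0.5 = 3, var_risk = NA,
                    var_ratio = 4, mean_risk_cases = 4,
                    mean_risk_noncases = 4, slope = 4, risk_p10 = 4,
                    risk_p90 = 4, rr = 2, range = 4))
}

# 12 improvement scenarios: K, Vold, Vnew, NRI, AUC increase, IDI
printed_table4 <- function() {
  m <- rbind(
    c(0.05, 0.05, 0.10, 0.099, 0.055, 0.014),
    c(0.05, 0.05, 0.15, 0.195, 0.096, 0.029),
    c(0.05, 0.10, 0.15, 0.102, 0.041, 0.015),
    c(0.05, 0.10, 0.20, 0.202, 0.075, 0.032),
    c(0.05, 0.20, 0.25, 0.104, 0.029, 0.019),
    c(0.05, 0.20, 0.30, 0.201, 0.054, 0.040),
    c(0.10, 0.05, 0.10, 0.166, 0.050, 0.019),
    c(0.10, 0.05, 0.15, 0.306, 0.089, 0.040),
    c(0.10, 0.10, 0.15, 0.142, 0.038, 0.021),
    c(0.10, 0.10, 0.20, 0.262, 0.070, 0.043),
    c(0.10, 0.20, 0.25, 0.109, 0.028, 0.024),
    c(0.10, 0.20, 0.30, 0.205, 0.053, 0.049))
  colnames(m) <- c("K", "Vold", "Vnew", "nri", "auc_increase", "idi")
  as.data.frame(m)
}

# Nine diseases: printed lifetime risk, variance explained, and indices.
# K and Vm are themselves rounded prints, so acceptance compares against
# the interval spanned by half-ulp input perturbations.
printed_table5 <- function() {
  dis <- c("Bipolar", "CaBreast", "CAD", "Crohn", "CaProstate",
           "SCZ", "SLE", "DM1", "DM2")
  list(
    disease = dis,
    K = c(0.021, 0.127, 0.3365, 0.0060, 0.156, 0.0072, 0.0031, 0.0066,
          0.2895),
    K_ulp = c(1e-3, 1e-3, 1e-4, 1e-4, 1e-3, 1e-4, 1e-4, 1e-4, 1e-4),
    Vm = c(0.0214, 0.057, 0.123, 0.074, 0.125, 0.003, 0.087, 0.109, 0.118),
    Vm_ulp = c(1e-4, 1e-3, 1e-3, 1e-3, 1e-3, 1e-3, 1e-3, 1e-3, 1e-3),
    vals = list(
      auc_exact = c(0.600, 0.625, 0.662, 0.711, 0.680, 0.543, 0.741,
                    0.750, 0.661),
      auc_binormal_eq = c(0.600, 0.624, 0.658, 0.708, 0.675, 0.544, 0.738,
                          0.745, 0.657),
      auc_binormal = c(0.601, 0.626, 0.664, 0.712, 0.681, 0.544, 0.742,
                       0.751, 0.663),
      pce_0.1 = c(0.174, 0.181, 0.173, 0.298, 0.218, 0.130, 0.345, 0.353,
                  0.180),
      pce_0.2 = c(0.310, 0.322, 0.314, 0.471, 0.376, 0.246, 0.523, 0.535,
                  0.324),
      pce_0.5 = c(0.639, 0.656, 0.655, 0.788, 0.716, 0.562, 0.825, 0.835,
                  0.664),
      var_risk = c(5.68e-05, 2.56e-03, 1.66e-02, 2.66e-05, 7.62e-03,
                   1.28e-06, 1.05e-05, 5.24e-05, 1.41e-02),
      var_ratio = c(0.0028, 0.0231, 0.0745, 0.0045, 0.0578, 0.0002,
                    0.0034, 0.0079, 0.0687),
      mean_risk_cases = c(0.0237, 0.1472, 0.3859, 0.0104, 0.2048, 0.0074,
                          0.0065, 0.0145, 0.3383),
      mean_risk_noncases = c(0.0209, 0.1241, 0.3114, 0.0059, 0.1470,
                             0.0072, 0.0031, 0.0066, 0.2696),
      slope = c(0.0028, 0.0231, 0.0745, 0.0045, 0.0578, 0.0002, 0.0034,
                0.0079, 0.0687),
      risk_p10 = c(0.0124, 0.0682, 0.1759, 0.0015, 0.0588, 0.0058, 0.0005,
                   0.0011, 0.1444),
      risk_p90 = c(0.0310, 0.1950, 0.5119, 0.0122, 0.2754, 0.0087, 0.0067,
                   0.0148, 0.4517),
      rr = c(2.50, 2.86, 2.91, 8.32, 4.69, 1.49, 12.23, 13.92, 3.13),
      range = c(0.019, 0.127, 0.336, 0.011, 0.217, 0.003, 0.006, 0.014,
                0.307)
    ),
    decimals = c(auc_exact = 3, auc_binormal_eq = 3, auc_binormal = 3,
                 pce_0.1 = 3, pce_0.2 = 3, pce_0.5 = 3, var_risk = NA,
                 var_ratio = 4, mean_risk_cases = 4, mean_risk_noncases = 4,
                 slope = 4, risk_p10 = 4, risk_p90 = 4, rr = 2, range = 3))
}

# the 15 indices, in the order of the tables above
compute_indices <- function(K, Vm) {
  m <- disease_model(K, Vm)
  rs <- risk_summary(m)
  c(auc_exact = auc_exact(m),
    auc_binormal_eq = auc_binormal(m, equal_variance = TRUE),
    auc_binormal = auc_binormal(m, equal_variance = FALSE),
    pce_0.1 = proportion_cases_explained(m, 0.1),
    pce_0.2 = proportion_cases_explained(m, 0.2),
    pce_0.5 = proportion_cases_explained(m, 0.5),
    var_risk = rs$var_risk,
    var_ratio = rs$var_ratio,
    mean_risk_cases = rs$mean_risk_cases,
    mean_risk_noncases = rs$mean_risk_noncases,
    slope = rs$discrimination_slope,
    risk_p10 = unname(rs$risk_at_p[1]),
    risk_p90 = unname(rs$risk_at_p[2]),
    rr = rs$rr_between,
    range = rs$range_between)
}
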