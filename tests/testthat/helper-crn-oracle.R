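# Independent R-language oracle of the CRN membrane currents, written
# directly from the published model equations and parameterized from the
# package's versioned YAML constant record (so it also cross-checks the
# constants file against the compiled implementation).

crn_oracle_currents <- function(V, s, f_gto = 1, f_gcal = 1, f_gkr = 1) {
  k <- ionic_constants("crn")
  rtf <- k$physical$R * k$physical$T / k$physical$F
  g <- k$conductances; p <- k$pumps_exchangers
  ENa <- rtf * log(k$external$Na_o / s[["Nai"]])
  EK  <- rtf * log(k$external$K_o / s[["Ki"]])
  ECa <- rtf / 2 * log(k$external$Ca_o / s[["Cai"]])

  sig <- (exp(k$external$Na_o / 67.3) - 1) / 7
  fnak <- 1 / (1 + 0.1245 * exp(-0.1 * V / rtf) +
                 0.0365 * sig * exp(-V / rtf))
  egm <- exp((p$gamma - 1) * V / rtf)

  list(
    INa  = g$g_Na * s[["m"]]^3 * s[["h"]] * s[["j"]] * (V - ENa),
    IK1  = g$g_K1 * (V - EK) / (1 + exp(0.07 * (V + 80))),
    Ito  = f_gto * g$g_to * s[["oa"]]^3 * s[["oi"]] * (V - EK),
    IKur = (0.005 + 0.05 / (1 + exp(-(V - 15) / 13))) *
      s[["ua"]]^3 * s[["ui"]] * (V - EK),
    IKr  = f_gkr * g$g_Kr * s[["xr"]] * (V - EK) /
      (1 + exp((V + 15) / 22.4)),
    IKs  = g$g_Ks * s[["xs"]]^2 * (V - EK),
    ICaL = f_gcal * g$g_CaL * s[["d"]] * s[["f"]] * s[["fca"]] * (V - 65),
    IpCa = p$I_pCa_max * s[["Cai"]] / (0.0005 + s[["Cai"]]),
    INaK = p$I_NaK_max * fnak * k$external$K_o /
      (k$external$K_o + p$Km_Ko) /
      (1 + (p$Km_Nai / s[["Nai"]])^1.5),
    INaCa = p$I_NaCa_max *
      (exp(p$gamma * V / rtf) * s[["Nai"]]^3 * k$external$Ca_o -
         egm * k$external$Na_o^3 * s[["Cai"]]) /
      ((p$Km_Na^3 + k$external$Na_o^3) * (p$Km_Ca + k$external$Ca_o) *
         (1 + p$k_sat * egm)),
    IbNa = g$g_bNa * (V - ENa),
    IbCa = g$g_bCa * (V - ECa)
  )
}

# fibroblast total-current oracle for root finding (steady-state V with
# gates at their voltage steady states)
fb_oracle_total_current <- function(V) {
  k <- ionic_constants("maccannell")
  rtf <- with(ionic_constants("crn")$physical, R * T / F)
  ek <- rtf * log(k$concentrations$K_o / k$concentrations$K_i)
  ena <- rtf * log(k$concentrations$Na_o / k$concentrations$Na_i)
  r_inf <- 1 / (1 + exp(-(V + 20) / 11))
  s_inf <- 1 / (1 + exp((V + 23) / 7))
  ikv <- k$I_Kv$g_Kv * r_inf * s_inf * (V - ek)
  vk <- V - ek
  a <- 0.1 / (1 + exp(0.06 * (vk - 200)))
  b <- (3 * exp(2e-4 * (vk + 100)) + exp(0.1 * (vk - 10))) /
    (1 + exp(-0.5 * vk))
  ik1 <- k$I_K1$g_K1 * a / (a + b) * vk
  na15 <- k$concentrations$Na_i^1.5
  inak <- k$I_NaK$I_NaK_max * (k$concentrations$K_o /
                                 (k$concentrations$K_o + k$I_NaK$Km_K)) *
    (na15 / (na15 + k$I_NaK$Km_Na^1.5)) *
    (V - k$I_NaK$V_rev) / (V - k$I_NaK$B)
  ibna <- k$I_bNa$g_bNa * (V - ena)
  ikv + ik1 + inak + ibna
}
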