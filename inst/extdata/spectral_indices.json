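[
  {"name": "NDVI", "display_name": "NDVI",
   "formula": "(R800 - R680)/(R800 + R680)",
   "required_wavelengths_nm": [680, 800],
   "source": "Normalized difference vegetation index; Rouse et al. (1974), Tucker (1979)"},
  {"name": "GNDVI", "display_name": "GNDVI",
   "formula": "(R800 - R550)/(R800 + R550)",
   "required_wavelengths_nm": [550, 800],
   "source": "Green NDVI; Gitelson, Kaufman & Merzlyak (1996)"},
  {"name": "NDNI", "display_name": "NDNI",
   "formula": "(log(1/R1510) - log(1/R1680))/(log(1/R1510) + log(1/R1680))",
   "required_wavelengths_nm": [1510, 1680],
   "source": "Normalized difference nitrogen index; Serrano, Penuelas & Ustin (2002). Nominal wavelengths lie in the SWIR; unresolvable on a VNIR-only grid."},
  {"name": "NPQI", "display_name": "NPQI",
   "formula": "(R415 - R435)/(R415 + R435)",
   "required_wavelengths_nm": [415, 435],
   "source": "Normalized phaeophytinization index; Barnes et al. (1992)"},
  {"name": "EVI", "display_name": "EVI",
   "formula": "2.5*(R800 - R670)/(R800 + 6*R670 - 7.5*R475 + 1)",
   "required_wavelengths_nm": [475, 670, 800],
   "source": "Enhanced vegetation index; Huete et al. (2002)"},
  {"name": "Chlg", "display_name": "Chlg",
   "formula": "R780/R550 - 1",
   "required_wavelengths_nm": [550, 780],
   "source": "Green chlorophyll index CI_green; Gitelson, Gritz & Merzlyak (2003)"},
  {"name": "CRI1", "display_name": "CRI1",
   "formula": "1/R510 - 1/R550",
   "required_wavelengths_nm": [510, 550],
   "source": "Carotenoid reflectance index 1; Gitelson et al. (2002)"},
  {"name": "CRI2", "display_name": "CRI2",
   "formula": "1/R510 - 1/R700",
   "required_wavelengths_nm": [510, 700],
   "source": "Carotenoid reflectance index 2; Gitelson et al. (2002)"},
  {"name": "CRI3", "display_name": "CRI3",
   "formula": "(1/R510 - 1/R550)*R770",
   "required_wavelengths_nm": [510, 550, 770],
   "source": "NIR-scaled carotenoid reflectance index; Gitelson, Keydan & Merzlyak (2006)"},
  {"name": "CRI4", "display_name": "CRI4",
   "formula": "(1/R510 - 1/R700)*R770",
   "required_wavelengths_nm": [510, 700, 770],
   "source": "NIR-scaled carotenoid reflectance index; Gitelson, Keydan & Merzlyak (2006)"},
  {"name": "Datt6", "display_name": "Datt6",
   "formula": "R860/(R550*R708)",
   "required_wavelengths_nm": [550, 708, 860],
   "source": "Chlorophyll ratio; Datt (1998)"},
  {"name": "GMI1", "display_name": "GMI1",
   "formula": "R750/R550",
   "required_wavelengths_nm": [550, 750],
   "source": "Gitelson & Merzlyak index 1; Gitelson & Merzlyak (1997)"},
  {"name": "GMI2", "display_name": "GMI2",
   "formula": "R750/R700",
   "required_wavelengths_nm": [700, 750],
   "source": "Gitelson & Merzlyak index 2; Gitelson & Merzlyak (1997)"},
  {"name": "PARS", "display_name": "PARS",
   "formula": "R746/R513",
   "required_wavelengths_nm": [513, 746],
   "source": "Pigment analysis by reflectance spectra ratio; after Chappelle, Kim & McMurtrey (1992)"},
  {"name": "SR1", "display_name": "SR1",
   "formula": "R800/R675",
   "required_wavelengths_nm": [675, 800],
   "source": "Simple ratio; Blackburn (1998)"},
  {"name": "SR3", "display_name": "SR3",
   "formula": "R750/R550",
   "required_wavelengths_nm": [550, 750],
   "source": "Simple ratio (NIR/green); after Gitelson & Merzlyak (1997); same band pair as GMI1, kept under its conventional registry name"},
  {"name": "D1", "display_name": "D1",
   "formula": "D730/D706",
   "required_wavelengths_nm": [706, 730],
   "source": "First-derivative ratio; Zarco-Tejada et al. (2003)"},
  {"name": "D2", "display_name": "D2",
   "formula": "D705/D722",
   "required_wavelengths_nm": [705, 722],
   "source": "First-derivative ratio; Zarco-Tejada et al. (2003)"},
  {"name": "RDVI", "display_name": "RDVI",
   "formula": "(R800 - R670)/sqrt(R800 + R670)",
   "required_wavelengths_nm": [670, 800],
   "source": "Renormalized difference vegetation index; Roujean & Breon (1995)"},
  {"name": "RARSa", "display_name": "RARSa",
   "formula": "R675/R700",
   "required_wavelengths_nm": [675, 700],
   "source": "Ratio analysis of reflectance spectra, chlorophyll a; Chappelle, Kim & McMurtrey (1992)"},
  {"name": "RARSb", "display_name": "RARSb",
   "formula": "R675/(R650*R700)",
   "required_wavelengths_nm": [650, 675, 700],
   "source": "Ratio analysis of reflectance spectra, chlorophyll b; Chappelle, Kim & McMurtrey (1992)"},
  {"name": "RARSc", "display_name": "RARSc",
   "formula": "R760/R500",
   "required_wavelengths_nm": [500, 760],
   "source": "Ratio analysis of reflectance spectra, carotenoids; Chappelle, Kim & McMurtrey (1992)"},
  {"name": "SD_index", "display_name": "SD",
   "formula": "dsum(626, 795)",
   "required_wavelengths_nm": [626, 795],
   "source": "Sum of first-derivative reflectance over the red-edge region 626-795 nm, after Elvidge & Chen (1995); stored as SD_index to avoid collision with stalk diameter"},
  {"name": "PRI", "display_name": "PRI",
   "formula": "(R531 - R570)/(R531 + R570)",
   "required_wavelengths_nm": [531, 570],
   "source": "Photochemical reflectance index; Gamon, Penuelas & Field (1992)"},
  {"name": "SAVI", "display_name": "SAVI",
   "formula": "1.5*(R800 - R670)/(R800 + R670 + 0.5)",
   "required_wavelengths_nm": [670, 800],
   "source": "Soil-adjusted vegetation index, L = 0.5; Huete (1988)"},
  {"name": "OSAVI", "display_name": "OSAVI",
   "formula": "1.16*(R800 - R670)/(R800 + R670 + 0.16)",
   "required_wavelengths_nm": [670, 800],
   "source": "Optimized soil-adjusted vegetation index; Rondeaux, Steven & Baret (1996)"}
]
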