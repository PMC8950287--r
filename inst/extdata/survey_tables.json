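{
  "comment": "Published summary tables of the Cypripedium guttatum pollination survey (Manhangjae, Republic of Korea, 2018). The quantitative interaction matrix itself was never published; only these summaries were.",
  "plant_species": [
    "Polygonatum odoratum var. pluriflorum",
    "Ranunculus japonicus",
    "Viola mandshurica",
    "Rhododendron schlippenbachii",
    "Cypripedium guttatum",
    "Aruncus dioicus var. kamtschaticus",
    "Weigela florida",
    "Arabis gemmifera",
    "Taraxacum officinale",
    "Barbarea vulgaris",
    "Valeriana fauriei",
    "Cerastium holosteoides var. hallaisanensis"
  ],
  "pollinator_species": [
    "Eucera sp. 1",
    "Pristomyrmex pungens",
    "Ceratina flavipes",
    "Lasioglossum exiliceps",
    "Lasioglossum virideglaucum",
    "Lasioglossum duplex",
    "Lasioglossum miyabei",
    "Eristalomyia tenax",
    "Metasyrphus luniger",
    "Curculionidae sp. 1",
    "Oedemeridae sp. 1",
    "Elateridae sp. 1",
    "Vespidae sp. 1",
    "Parnassius stubbendorfii",
    "Bombylius major",
    "Carterocephalus silvicola",
    "Andrena sp. 1",
    "Apis mellifera",
    "Philopota nigroaenea"
  ],
  "plant_degrees": [2, 10, 0, 5, 1, 2, 4, 5, 1, 1, 7, 4],
  "plant_bc": [0.000, 0.238, null, 0.048, 0.000, 0.000, 0.000, 0.476, 0.000, 0.000, 0.238, 0.000],
  "plant_cc": [0.059, 0.106, null, 0.100, 0.095, 0.065, 0.095, 0.106, 0.078, 0.095, 0.106, 0.095],
  "pollinator_degrees": [1, 1, 1, 2, 8, 3, 2, 1, 5, 2, 3, 1, 1, 2, 2, 1, 2, 3, 1],
  "pollinator_bc": [0.000, 0.000, 0.000, 0.016, 0.259, 0.083, 0.153, 0.000, 0.176, 0.016, 0.188, 0.000, 0.000, 0.035, 0.024, 0.000, 0.005, 0.044, 0.000],
  "pollinator_cc": [0.030, 0.055, 0.055, 0.057, 0.070, 0.062, 0.047, 0.049, 0.068, 0.053, 0.063, 0.035, 0.044, 0.061, 0.057, 0.049, 0.047, 0.059, 0.042],
  "visit_durations_s": [55, 68, 60, 78, 67, 71, 57, 45],
  "hourly_dates": ["2018-05-28", "2018-05-31", "2018-06-04"],
  "hourly_windows": ["0900-1000", "1000-1100", "1100-1200", "1200-1300", "1300-1400", "1400-1500", "1500-1600"],
  "hourly_visits": [
    [0, 2, 2, 2, 1, 3, 0],
    [0, 0, 2, 1, 2, 3, 0],
    [0, 0, 0, 0, 0, 0, 0]
  ],
  "flowering_start_day": 147,
  "flowering_end_day": 157,
  "daily_params": [
    {"day": 146, "R": 8, "A": 14, "L": 25, "links_added": 0, "raw_nodf": 0.239, "max_nodf": 0.598, "nodf_c_printed": 1.571},
    {"day": 147, "R": 4, "A": 3, "L": 5, "links_added": 3, "raw_nodf": 0.333, "max_nodf": 0.889, "nodf_c_printed": 1.668},
    {"day": 149, "R": 10, "A": 9, "L": 17, "links_added": 3, "raw_nodf": 0.216, "max_nodf": 0.469, "nodf_c_printed": 2.495},
    {"day": 154, "R": 4, "A": 8, "L": 12, "links_added": 1, "raw_nodf": 0.353, "max_nodf": 0.647, "nodf_c_printed": 1.933}
  ]
}
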