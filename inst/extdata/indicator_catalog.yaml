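# Catalog of commercial geospatial availability indicators.
#
# Each categorical indicator lists its ordered precision/availability levels
# from WORST to BEST, together with the published number of countries at each
# level out of the 183-country reference set. The counts serve two purposes:
# they document the observed international distribution, and the synthetic
# generator uses them as bin widths so simulated data reproduce the same
# marginal distribution of ties.
#
# missing_policy: worst               -> an absent coverage statement scores
#                                        at the worst level (absence of a
#                                        published service is itself a level)
#                 fallback_population -> substitute the national population
#                 zero                -> substitute zero

countries_total: 183

indicators:

  # ---- geocoding domain -------------------------------------------------
  esri_geocoding:
    label: "ESRI"
    domain: geocoding
    kind: ordinal
    missing_policy: worst
    levels:
      - {label: "Level 4", count: 74}   # imprecise: admin-boundary centroids
      - {label: "Level 3", count: 51}
      - {label: "Level 2", count: 16}
      - {label: "Level 1", count: 42}   # precise or street-interpolated

  pitney_bowes:
    label: "Pitney Bowes"
    domain: geocoding
    kind: ordinal
    missing_policy: worst
    levels:
      - {label: "Not specified", count: 1}
      - {label: "Administrative boundaries or place-names", count: 29}
      - {label: "Post code", count: 34}
      - {label: "Street-level geocoding", count: 60}
      - {label: "Address geocoding", count: 39}
      - {label: "Precise address point geocoding", count: 20}

  tomtom_geocoding:
    label: "TomTom"
    domain: geocoding
    kind: ordinal
    missing_policy: worst
    levels:
      - {label: "Locality", count: 44}
      - {label: "Street-level", count: 77}
      - {label: "Interpolated address", count: 20}
      - {label: "Address point", count: 42}

  mapbox_geocoding:
    label: "MapBox"
    domain: geocoding
    kind: ordinal
    missing_policy: worst
    # counts sum to the 183-country total
    levels:
      - {label: "No service", count: 78}
      - {label: "Place-name", count: 60}
      - {label: "Postcode", count: 20}
      - {label: "Address geocoding", count: 25}

  loqate:
    label: "Loqate"
    domain: geocoding
    kind: ordinal
    missing_policy: worst
    levels:
      - {label: "Locality", count: 19}
      - {label: "Thoroughfare", count: 68}
      - {label: "Premises", count: 44}
      - {label: "Premises - point", count: 52}

  # ---- patient travel domain -------------------------------------------
  esri_here_travel:
    label: "ESRI / HERE"
    domain: travel
    kind: ordinal
    missing_policy: worst
    levels:
      - {label: "Minimal street coverage", count: 24}
      - {label: "Limited street coverage", count: 73}
      - {label: "Posted speed limits", count: 15}
      - {label: "Historical traffic", count: 20}
      - {label: "Live traffic", count: 40}
      - {label: "Predictive traffic", count: 11}

  google_travel:
    label: "Google Maps"
    domain: travel
    kind: travel_composite
    # Five components each scored good = 2, approximate = 1, otherwise 0;
    # the composite is the sum, range 0-10. Reference counts per component;
    # walking and driving directions have universal good coverage.
    components:
      traffic:      {good: 91,  approximate: 1,   none: 91}
      speed_limits: {good: 11,  approximate: 166, none: 6}
      cycling:      {good: 21,  approximate: 0,   none: 162}
      walking:      {good: 183, approximate: 0,   none: 0}
      driving:      {good: 183, approximate: 0,   none: 0}

  igeolise:
    label: "iGeolise TravelTime"
    domain: travel
    kind: ordinal
    missing_policy: worst
    levels:
      - {label: "Travel times unavailable", count: 157}
      - {label: "Travel times for driving only", count: 3}
      - {label: "Travel times for public transport and driving", count: 23}

  tomtom_travel:
    label: "TomTom"
    domain: travel
    kind: ordinal
    missing_policy: worst
    levels:
      - {label: "No online routing", count: 69}
      - {label: "Online routing without traffic", count: 57}
      - {label: "Online routing with traffic flows only", count: 15}
      - {label: "Online routing with traffic incidents and traffic flows", count: 42}

  mapbox_travel:
    label: "MapBox"
    domain: travel
    kind: ordinal
    missing_policy: worst
    levels:
      - {label: "Traffic layer unavailable", count: 150}
      - {label: "Traffic layer available", count: 33}

  # ---- neighbourhood characterisation domain ---------------------------
  mb_mean_population:
    label: "Michael Bauer - average population per areal unit"
    domain: neighbourhood
    kind: numeric
    direction: lower_better          # smaller areal units = finer statistics
    missing_policy: fallback_population
    reference: {median: 130000, q05: 411, q95: 23801400}

  mb_attribute_groups:
    label: "Michael Bauer - no. of areal attribute groups"
    domain: neighbourhood
    kind: count
    direction: higher_better
    missing_policy: zero
    reference: {mean: 4, q05: 0, q95: 9}

  geodemographic:
    label: "Geodemographic classification/demographic data availability"
    domain: neighbourhood
    kind: availability_count
    # count of available products, range 0-3; reference = countries covered
    components:
      mosaic_available: 24
      cameo_available: 39
      maptitude_available: 13
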