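{
  "report_version": 1,
  "n": 5,
  "alpha": 0.05,
  "level": 0.95,
  "n_flipped": 1,
  "observed_significant": 2,
  "methods": [
    {
      "method": "N",
      "qs": -0.744864791689965,
      "ls": 0.137520902324919,
      "crps": 0.15674508248325,
      "p_cal": 0.379731320517543,
      "coverage": 1,
      "ks_p": 0.0570623783882024,
      "observed": 2,
      "expected": 4.15141352414698,
      "chisq_p": 0.0103746934068677,
      "bs": 0.407647020855537,
      "bs_norm": -0.698529253564738,
      "spiegelhalter": 2.68212013982315,
      "spiegelhalter_p": 0.00731571819150896,
      "slope": 1.09887715472072,
      "slope_low": -2.21451433369067,
      "slope_high": 4.4122686431321,
      "slope_estimable": true,
      "auc": 0.666666666666667,
      "auc_low": 0.0695377104341602,
      "auc_high": 0.981659030628534
    },
    {
      "method": "S",
      "qs": -1.09683891426413,
      "ls": -0.104781189824245,
      "crps": 0.127086215188124,
      "p_cal": 0.788658650460606,
      "coverage": 1,
      "ks_p": 0.184378621617892,
      "observed": 2,
      "expected": 3.84563310587576,
      "chisq_p": 0.0501444451260268,
      "bs": 0.355251419180754,
      "bs_norm": -0.480214246586475,
      "spiegelhalter": 1.98544802702105,
      "spiegelhalter_p": 0.0470946470882533,
      "slope": 1.17384035501407,
      "slope_low": -2.17441652635134,
      "slope_high": 4.52209723637947,
      "slope_estimable": true,
      "auc": 0.666666666666667,
      "auc_low": 0.0695377104341602,
      "auc_high": 0.981659030628534
    },
    {
      "method": "H",
      "qs": -0.900510639273939,
      "ls": 0.0756882328883226,
      "crps": 0.153597873318391,
      "p_cal": 0.770792503406294,
      "coverage": 1,
      "ks_p": 0.0642859645249881,
      "observed": 2,
      "expected": 3.99783973754506,
      "chisq_p": 0.0256250934562344,
      "bs": 0.382259965988337,
      "bs_norm": -0.592749858284737,
      "spiegelhalter": 2.31546310897178,
      "spiegelhalter_p": 0.0205876012326993,
      "slope": 1.13115935046994,
      "slope_low": -2.25492581442572,
      "slope_high": 4.51724451536561,
      "slope_estimable": true,
      "auc": 0.666666666666667,
      "auc_low": 0.0695377104341602,
      "auc_high": 0.981659030628534
    },
    {
      "method": "SH",
      "qs": -1.29347687697658,
      "ls": -0.166284361775975,
      "crps": 0.118912516490812,
      "p_cal": 0.886124348630633,
      "coverage": 1,
      "ks_p": 0.248729359676243,
      "observed": 2,
      "expected": 3.60276220514229,
      "chisq_p": 0.110186852927816,
      "bs": 0.321795360026337,
      "bs_norm": -0.340814000109739,
      "spiegelhalter": 1.55522730165539,
      "spiegelhalter_p": 0.119891944259799,
      "slope": 1.13040894727637,
      "slope_low": -2.10306200022578,
      "slope_high": 4.36387989477851,
      "slope_estimable": true,
      "auc": 0.666666666666667,
      "auc_low": 0.0695377104341602,
      "auc_high": 0.981659030628534
    },
    {
      "method": "PM",
      "qs": null,
      "ls": null,
      "crps": null,
      "p_cal": null,
      "coverage": null,
      "ks_p": null,
      "observed": 2,
      "expected": 2.8,
      "chisq_p": 0.471063361733219,
      "bs": 0.161,
      "bs_norm": 0.329166666666667,
      "spiegelhalter": -0.816496580927726,
      "spiegelhalter_p": 0.414216178242525,
      "slope": null,
      "slope_low": null,
      "slope_high": null,
      "slope_estimable": false,
      "auc": 1,
      "auc_low": null,
      "auc_high": null
    }
  ],
  "calibration_tests": [
    {
      "test": "ls_z",
      "statistic": 1.02661947522598,
      "p_value": 0.304599679908495,
      "applicable": true,
      "method": "N"
    },
    {
      "test": "crps_z",
      "statistic": 1.07317969056926,
      "p_value": 0.283190501186047,
      "applicable": true,
      "method": "N"
    },
    {
      "test": "ls_reg",
      "statistic": 1.08159179837633,
      "p_value": 0.582284628036611,
      "applicable": true,
      "method": "N"
    },
    {
      "test": "crps_reg",
      "statistic": 1.38849425031984,
      "p_value": 0.499450330058675,
      "applicable": true,
      "method": "N"
    },
    {
      "test": "ls_z",
      "statistic": 0.36392251773325,
      "p_value": 0.715915869238653,
      "applicable": true,
      "method": "S"
    },
    {
      "test": "crps_z",
      "statistic": 0.40173391961386,
      "p_value": 0.687879858555952,
      "applicable": true,
      "method": "S"
    },
    {
      "test": "ls_reg",
      "statistic": 0.157644302540001,
      "p_value": 0.924204278386755,
      "applicable": true,
      "method": "S"
    },
    {
      "test": "crps_reg",
      "statistic": 0.260892159638956,
      "p_value": 0.877703817621141,
      "applicable": true,
      "method": "S"
    },
    {
      "test": "ls_z",
      "statistic": 0.367772861518369,
      "p_value": 0.713042606331413,
      "applicable": true,
      "method": "H"
    },
    {
      "test": "crps_z",
      "statistic": 0.478929124219322,
      "p_value": 0.631989050972009,
      "applicable": true,
      "method": "H"
    },
    {
      "test": "ls_reg",
      "statistic": 0.135342318653499,
      "p_value": 0.934567746939557,
      "applicable": true,
      "method": "H"
    },
    {
      "test": "crps_reg",
      "statistic": 0.252743732605344,
      "p_value": 0.881287064879262,
      "applicable": true,
      "method": "H"
    },
    {
      "test": "ls_z",
      "statistic": -0.261866587431227,
      "p_value": 0.793424300299349,
      "applicable": true,
      "method": "SH"
    },
    {
      "test": "crps_z",
      "statistic": -0.208411310387751,
      "p_value": 0.834907825809171,
      "applicable": true,
      "method": "SH"
    },
    {
      "test": "ls_reg",
      "statistic": 0.0690665339236835,
      "p_value": 0.966056201397134,
      "applicable": true,
      "method": "SH"
    },
    {
      "test": "crps_reg",
      "statistic": 0.0411850122202122,
      "p_value": 0.979618071625711,
      "applicable": true,
      "method": "SH"
    }
  ]
}
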