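{
  "type": "FeatureCollection",
  "features": [
    {
      "type": "Feature",
      "properties": {"city_id": "DEMO1"},
      "geometry": {
        "type": "LineString",
        "coordinates": [[-74.810, 4.300], [-74.790, 4.300]]
      }
    },
    {
      "type": "Feature",
      "properties": {"city_id": "DEMO1"},
      "geometry": {
        "type": "MultiLineString",
        "coordinates": [
          [[-74.800, 4.292], [-74.800, 4.308]],
          [[-74.795, 4.292], [-74.795, 4.308]]
        ]
      }
    }
  ]
}
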