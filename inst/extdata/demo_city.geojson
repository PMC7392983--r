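{
  "type": "FeatureCollection",
  "features": [
    {
      "type": "Feature",
      "properties": {"city_id": "DEMO1", "country": "CO"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[
          [-74.812, 4.291], [-74.788, 4.291], [-74.788, 4.309],
          [-74.812, 4.309], [-74.812, 4.291]
        ]]
      }
    }
  ]
}
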