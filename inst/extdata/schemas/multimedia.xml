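<?xml version="1.0" encoding="UTF-8"?>
<!-- Simple Multimedia extension: media items related many-to-one to core
     records (images, sounds, videos attached to an occurrence or taxon). -->
<extension title="Simple Multimedia"
           rowType="http://rs.gbif.org/terms/1.0/Multimedia">
  <property name="type" qualName="http://purl.org/dc/terms/type"/>
  <property name="format" qualName="http://purl.org/dc/terms/format"/>
  <property name="identifier" qualName="http://purl.org/dc/terms/identifier"/>
  <property name="references" qualName="http://purl.org/dc/terms/references"/>
  <property name="title" qualName="http://purl.org/dc/terms/title"/>
  <property name="description" qualName="http://purl.org/dc/terms/description"/>
  <property name="created" qualName="http://purl.org/dc/terms/created"/>
  <property name="creator" qualName="http://purl.org/dc/terms/creator"/>
  <property name="contributor" qualName="http://purl.org/dc/terms/contributor"/>
  <property name="publisher" qualName="http://purl.org/dc/terms/publisher"/>
  <property name="audience" qualName="http://purl.org/dc/terms/audience"/>
  <property name="source" qualName="http://purl.org/dc/terms/source"/>
  <property name="license" qualName="http://purl.org/dc/terms/license"/>
  <property name="rightsHolder" qualName="http://purl.org/dc/terms/rightsHolder"/>
</extension>
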